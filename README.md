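# caspike

Multiscale stochastic simulation of intracellular Ca²⁺ spiking driven by
single-channel noise.

Repetitive Ca²⁺ spikes in astrocytes (and many other cell types) are
sequences of *random* interspike intervals: the randomness of individual
IP₃ receptor state transitions survives to the whole-cell level because
steep concentration microdomains couple the channels of a cluster
strongly but neighbouring clusters only weakly. `caspike` is for
modellers who want to follow that hierarchy explicitly — channel →
cluster → cell — without a spatial grid:

* **Channels** are DeYoung–Keizer Markov chains: each of the four
  subunits is a vertex (i, j, k) of a binary cube (IP₃ bound, activating
  Ca²⁺ bound, inhibiting Ca²⁺ bound), a channel conducts when at least
  three subunits are in the active state (1,1,0), and transitions are
  sampled exactly under piecewise-constant local concentrations.
* **Clusters** are quasi-static point sources with current
  `I(n) = n k₁ (E − c) / (1 + n k₁ (1/D_E + 1/D_c)/(4π R_s √n))`,
  the stationary two-domain source solution with local lumenal
  depletion; one open channel carries 0.12 pA at rest.
* **The cell** is a linearized three-species reaction–diffusion field
  (free Ca²⁺, mobile buffer, immobile buffer) in a 10 µm sphere with a
  no-flux membrane, solved analytically: an exact screened static kernel
  plus a spherical-eigenmode transient remainder
  (`j_l(k r) P_l(cos γ)` modes with three temporal decay rates each),
  coupled to a well-mixed ER store by pump, leak and the channel
  currents. Total cell calcium is conserved by construction.
* **Statistics**: spike detection, ISI moments, the σ–T_av regression
  whose slope-1 line with a ~20 s axis offset is the signature of
  Poissonian spike generation after a deterministic refractory period,
  population slopes per condition, and a surrogate ISI generator.

## Worked example

Simulate one standard cell (47 clusters of 4–16 channels scattered with
1–7 µm nearest-neighbour distances, resting Ca²⁺ 50 nM, IP₃ 0.1 µM) for
five minutes and read off its spike statistics:

```r
library(caspike)
cfg <- sim_config(t_end = 300, seed = 7)
ts  <- run_cell(cfg, verbose = TRUE)
#> run_cell: 47 clusters, 433 channels, 300 s; 2780733 events, 163788 refreshes
ts
#> ca_timeseries: 3000 samples over 300 s; 50366 source events
#>   c_avg range [uM]: 0.0570 0.6083

ss <- spike_stats_for_run(ts)   # threshold c0 + 0.07 uM, 10 s debounce
length(ss$train)
#> [1] 12
unlist(ss$stats)
#>     T_av    sigma    n_isi
#> 23.40909 16.42610 11.00000
```

2.8 million subunit transitions drive 50 thousand channel open/close
events; the whole-cell average spikes to ≈ 0.6 µM, 12 spikes are
detected, and this cell's mean ISI is ≈ 23 s with σ ≈ 16 s — a random
spike sequence, not a clock. Populations of such cells
across a grid of resting Ca²⁺ and IP₃ levels trace out the σ–T_av
relation; `population_configs()` / `run_isi_population()` /
`population_regression()` run those protocols at any scale, and
`surrogate_trains()` provides the analytic reference (slope 1, axis
offset = refractory period).

A thin command-line front end is installed at `inst/exec/caspike`
(`simulate`, `modes`, `spikes`, `experiment`, `fixtures`), reading
plain-text `key = value` configurations with explicit unit suffixes and
writing tab-separated tables plus a JSON run manifest that reproduces a
run bit-for-bit.

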