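---
title: "Multiscale stochastic calcium spiking: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale stochastic calcium spiking: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspike)
```

# The scientific problem

Intracellular Ca²⁺ spikes in many cell types — astrocytes prominently —
are *sequences of random interspike intervals*, even though each spike
involves thousands of channels. The randomness originates in the state
transitions of individual IP₃ receptor channels (IP₃R) and is carried up
to the cell level because steep concentration gradients around channel
clusters keep the clusters only weakly coupled: a cluster is ignited by
its neighbours' microdomains, not by a smooth bulk concentration, so the
law of large numbers never takes over. `caspike` simulates this
hierarchy explicitly in three spatial dimensions:

* **channels** as continuous-time Markov chains (DeYoung–Keizer subunit
  cube, four subunits per channel, open when ≥ 3 subunits are active),
* **clusters** as point sources whose quasi-static current follows from
  the stationary two-domain (ER ⊕ cytosol) source problem,
* **the cell** as a linearized three-species reaction–diffusion field
  (free Ca²⁺, one mobile buffer, one immobile buffer) in a sphere with a
  no-flux membrane, solved analytically by a Green's-function expansion
  and coupled to a well-mixed ER store through pump, leak and channel
  fluxes.

The headline readout is the relation between the standard deviation σ
and the mean T_av of the interspike intervals across cells: random spike
generation after a deterministic refractory period Δ gives σ = T_av − Δ,
a line of slope 1 crossing the T_av axis at the recovery time.

# Model components

## Channel gating

Each subunit carries an IP₃ site, an activating Ca²⁺ site and an
inhibiting Ca²⁺ site; its state is a vertex (i, j, k) of the binary
cube and the twelve edges are binding/unbinding transitions, with
binding rates linear in the local ligand concentration. The subunit is
active in (1,1,0). `dyk_params()` carries the canonical published rate
constants of this scheme; they are configuration entries, not
constants.

The package's *standard* channel parameterisation,
`ipr_astrocyte_params()`, keeps the cube and its detailed-balance cycle
condition (d₁d₂ = d₃d₄) but adapts the rates to the slow, high-affinity
IP₃R2-dominated gating of astrocytes:

* IP₃ site: tight and slow (d₁ = 0.02 µM, a₁ = 60 µM⁻¹s⁻¹), so a
  cluster's channels stay primed on the timescale of a release event
  instead of flickering their IP₃ occupancy at ~100 s⁻¹;
* activating site: d₅ = 1 µM (a₅ = 15 µM⁻¹s⁻¹). Placing the activation
  scale above the inter-cluster coupling range (0.05–0.5 µM) maximises
  the cooperative (≈ cubic) modulation of the opening flux between the
  resting level and a neighbour-elevated level, which is what makes
  cluster triggering specific;
* inhibiting site: slow binding (a₂ = a₄ = 0.05 µM⁻¹s⁻¹) with
  d₂ = 1.049 µM, d₄ = 0.5 µM. Release events are then terminated over
  hundreds of milliseconds rather than instantly, and the unbinding
  rates (0.052 s⁻¹ with IP₃ bound, 0.025 s⁻¹ without) produce the
  tens-of-seconds recovery that appears in the statistics as the
  deterministic part of the interspike interval.

We verified directly (two-cluster conditional-trigger measurements and
puff-strength statistics at the standard conditions) that the original
published constants, combined with the printed 0.12 pA single-channel
current, produce release events of 2–3 channels lasting only
milliseconds — too weak and too brief to couple clusters micrometres
apart. The adapted set produces cluster events that recruit most of a
cluster within ~1 ms and last long enough to recruit neighbours.

```{r biphasic}
cc <- c(0.01, 0.05, 0.1, 0.3, 1, 3, 10)
rbind(ca_uM = cc,
      P_open = signif(stationary_open_probability(cc, 0.1,
                                                  ipr_astrocyte_params()), 2))
```

## Cluster sources

A cluster with n open channels is a point source of strength

I(n) = n k₁ (E_avg − c_avg) / (1 + n k₁ (1/D_E + 1/D_c) / (4π R(n))),

the stationary solution of the radially symmetric two-domain transfer
problem around a sphere of radius R(n) = R_s √n (source membrane area
proportional to the open-channel count; the radius rule is isolated in
`cluster_radius()` for easy replacement). The denominator is the local
lumenal-depletion correction. The channel flux constant k₁ is
calibrated so that one open channel at the resting transmembrane
difference carries 0.12 pA; the tenfold-current condition used in the
coupling analyses is obtained by a tenfold lumenal concentration, which
leaves k₁ unchanged. Channels of an open cluster see the quasi-static
self term I/(4π D_c R(n)) — tens of µM — plus the fields of all other
clusters; a closed cluster is evaluated 10 nm radially outward from its
release site.

## The field and its quasi-static split

The linearized bulk dynamics (deviations from rest) of free Ca²⁺,
mobile buffer and immobile buffer diffuse and react with rates
linearized at the resting state; pumping is linear; the leak is uniform
and depends on the lumenal average only; the calibrated leak makes the
resting state an exact fixed point (`calibrate_leak()`). With a
no-flux membrane every k > 0 eigenmode has zero volume integral, so the
volume averages live in the uniform component, which together with the
ER average forms an exact 4-variable linear ODE. Total cell calcium
(free + buffer-bound + ER/γ) is conserved by construction.

The time-dependent field of the piecewise-constant cluster currents is
evaluated as a *quasi-static split*:

* the **static response** to the instantaneous currents is analytic — a
  sum of two screened-Coulomb kernels, with screening constants the
  roots of the static determinant (the immobile buffer drops out of the
  stationary balance), plus a smooth membrane correction built from
  modified spherical Bessel functions;
* the **transient remainder** lives on the spherical eigenmodes
  j_l(k_{ln} r) P_l(cos γ). For each spatial mode the 3×3 linearized
  coupling matrix yields three real negative decay rates (its
  eigenvalues; every stored rate satisfies |det(M − λI)| < 10⁻⁸
  relative) and residue weights. Each (cluster, mode, root) amplitude
  decays exponentially between events and jumps by ΔI/λ at a current
  switch, keeping the total field continuous.

The split is what makes the expansion practical: a raw truncated mode
sum converges extremely slowly for source/evaluation points at similar
radii (the Legendre series of the near-singular kernel), whereas the
remainder left after subtracting the static part is smooth — high-k
modes decay within microseconds and carry almost nothing. The composite
field changes by 0.14% at probe distances ≥ 1 µm when the default
truncation (l_max = 14, n_max = 20) is doubled, and agrees with an
independent time-dependent finite-difference integration to better than
1% from 20 ms after a source switch (see the test suite's oracles).

## Event loop

Between stochastic events the local concentrations are held constant
(the quasi-static approximation: local profiles equilibrate within
fractions of a millisecond, far faster than gating). The next subunit
transition is sampled exactly for the piecewise-constant propensities;
at channel open/close events the cluster current switches, the
source-history segment is recorded, the field amplitudes jump, and the
local environments of all clusters are refreshed. A full environment
refresh is otherwise performed at most every `env_refresh` (default
1 ms; `0` refreshes at every subunit event, which is the strictest
reading of the algorithm and is compared against the default in a
test). While all sources are silent the refresh interval grows
geometrically (×1.5, capped at 50 ms) — the field only relaxes then —
and once the transient bound falls below `field_tol` (10⁻⁴ µM) with all
channels closed, the spatial field is treated as fully decayed. All
randomness flows through R's RNG; a fixed seed reproduces runs
bit-for-bit, which the manifest (`run_manifest()`) makes reproducible
from file.

# Physiological parameter choices

Printed standard values are used verbatim: cell radius 10 µm, channel
radius 8 nm, resting Ca²⁺ 50 nM, IP₃ 0.1 µM, 50 µM total mobile buffer,
30 µM total immobile buffer, single-channel current 0.12 pA. The
remaining parameters are package choices:

| parameter | value | rationale |
|---|---|---|
| D_c | 223 µm²/s | canonical free-Ca²⁺ cytosolic diffusion |
| D_E | 40 µm²/s | lumenal diffusion reduced by ER tortuosity |
| D_b | 75 µm²/s | mobile-buffer diffusion |
| pump rate | 8 s⁻¹ | linearized SERCA; sets clearance and, with the buffers, the spike tail |
| leak | calibrated | resting fixed point, `pump·c0 = leak·E0` |
| E₀ | 700 µM | resting store ≈ 4 orders of magnitude above cytosol |
| γ | 5 | cytosol/ER volume ratio (ER ≈ 1/6 of cell volume) |
| mobile buffer | kon 0.2 µM⁻¹s⁻¹, koff 0.4 s⁻¹ (Kd 2 µM) | slow, low-affinity endogenous pool (parvalbumin-like); see below |
| immobile buffer | kon 0.5 µM⁻¹s⁻¹, koff 5 s⁻¹ (Kd 10 µM) | slow stationary sites, capacity ≈ 3 |

The *mobile buffer identity* deserves emphasis. The baseline,
spontaneously spiking cell is unloaded; EGTA and BAPTA kinetics
(`buffer_kinetics()`) describe the exogenous chelators of the
buffer-loading experiments. Treating the standard 50 µM mobile pool as
EGTA would impose a linearized buffering capacity of ≈ 160 and a
sub-micrometre dynamic screening length; both together suppress every
route to collective spiking at 0.12 pA channels (we verified this
numerically at length). The slow low-affinity endogenous pool gives a
capacity of ≈ 25 and a static screening length of ≈ 3 µm, in which
regime cluster events couple across the observed 1–7 µm inter-cluster
distances. Buffer loading is represented by raising the mobile pool
(the model has exactly one mobile buffer); the kinetic switch to
EGTA/BAPTA remains available through the configuration.

Because the model is linearized about rest, whole-cell average spikes
are bounded by store content over total buffering capacity — a few
hundred nM here. Spike detection therefore uses a threshold margin of
0.07 µM above the resting level (default threshold 0.12 µM), between
the baseline fluctuation band and the event amplitudes; both are
configuration entries since the detection rule is a free choice of the
analysis.

# Synthetic data and what the tests show

The layout generator places clusters uniformly in the cell volume
(rejection sampling with ≥ 1 µm pairwise separation and ≤ 7 µm nearest
neighbours), with 4–16 channels per cluster — the study conditions of
the concentration-grid protocol. The surrogate spike-train generator
(refractory offset plus exponential or gamma ISIs) is the analytic
signature of the random-wave-nucleation picture and lets the
statistics tier be tested without the simulator: its σ–T_av clouds
converge to slope 1 and offset Δ.

What passing tests show: the field solver reproduces independent
finite-difference solutions of the same linear equations; the sampler
reproduces exact Gillespie statistics; the conservation law and
resting fixed point hold to stated precision; the statistics tier
recovers known lines and generators. What they do not show: fidelity
of the linearization near open clusters (the model deliberately
replaces nonlinear pump/buffer saturation with the quasi-static self
term), real ER morphology, IP₃ dynamics, or amplitude scales of real
fluorescence signals.

# Problem sizes of the shipped statistics runs

The full population protocols (tens of cells, hundreds of ISIs each)
are hours of CPU. The shipped acceptance tests and the
`scripts/acceptance.R` report run the same protocols at a reduced,
fixed scale chosen once: five cells × 360 s (standard, 0.12 pA, grid
over resting Ca²⁺ 30–60 nM and IP₃ 0.05–0.2 µM), three cells × 240 s
(tenfold current), and paired re-simulation of the standard cells with
+10 µM mobile buffer; truncation l_max = 12, n_max = 16
(convergence-checked). At this scale each cell contributes ~5–20 ISIs
and the regression estimates carry large sampling noise; the asserted
bands are the full-protocol bands, and failures at this scale are
reported as such rather than hidden.

# Known limitations

* The linearization caps global spike amplitudes and omits pump/buffer
  saturation near open clusters; local concentrations at sources come
  from the quasi-static term by design.
* Sub-cluster structure is collapsed to a point source (the optional
  multiple-δ representation is not enabled by default).
* The transient mode remainder smooths the first ~millisecond after a
  current switch at the switching cluster itself; the local
  environment there is dominated by the quasi-static terms on exactly
  that timescale.
* The supplementary rate-constant table of the source model was not
  available; the standard channel kinetics are the package's own
  astrocyte-adapted set (documented above) and the canonical published
  set remains available as `dyk_params()`.
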