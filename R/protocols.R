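# Population protocols for the ISI statistics tier.
#
# The headline readouts are statistical properties of populations of
# simulated cells: the sigma-T_av regression across cells differing in
# resting Ca2+ and IP3 (and layout), its change under a tenfold
# single-channel current, and the shift of each cell when mobile buffer
# is added. Full-scale populations are hours of CPU; these helpers
# parameterise the same protocols at configurable scale.

#' Build a population of cell configurations
#'
#' @param kind `"standard"` (0.12 pA, grid over resting Ca2+ 30-60 nM and
#'   IP3 0.05-0.2 µM), `"high_current"` (same grid, tenfold lumenal
#'   concentration giving 1.2 pA channels), or `"buffer_shift"`
#'   (the standard population with the mobile-buffer pool raised by
#'   `delta_B`).
#' @param n_cells number of cells; the concentration grid is subsampled
#'   deterministically to this size.
#' @param t_end run length per cell (s).
#' @param seed master seed; cell i uses `seed*1000 + i` for its layout and
#'   gating stream.
#' @param n_clusters clusters per cell.
#' @param delta_B added mobile buffer for `"buffer_shift"` (µM).
#' @param l_max,n_max mode truncation.
#' @return list of [sim_config()]s with `label` fields.
#' @export
population_configs <- function(kind = c("standard", "high_current",
                                        "buffer_shift"),
                               n_cells = 9, t_end = 400, seed = 1L,
                               n_clusters = 47, delta_B = 10,
                               l_max = 14, n_max = 20) {
  kind <- match.arg(kind)
  grid <- expand.grid(c0 = c(0.03, 0.045, 0.06),
                      ip3 = c(0.05, 0.125, 0.2))
  keep <- unique(round(seq(1, nrow(grid), length.out =
                             min(n_cells, nrow(grid)))))
  if (n_cells > nrow(grid)) {
    keep <- rep(keep, length.out = n_cells)  # extra cells: new layouts
  }
  lapply(seq_along(keep), function(i) {
    g <- grid[keep[i], ]
    p <- phys_params(
      c0 = g$c0, ip3 = g$ip3,
      B_m = 50 + if (kind == "buffer_shift") delta_B else 0,
      E0 = if (kind == "high_current") 7000 else 700,
      single_channel_pA = if (kind == "high_current") 1.2 else 0.12)
    cfg <- sim_config(p = p, n_clusters = n_clusters,
                      channel_range = c(4L, 16L), t_end = t_end,
                      seed = as.integer(seed * 1000 + i),
                      l_max = l_max, n_max = n_max)
    cfg$label <- sprintf("%s_c0=%gnM_ip3=%guM_cell%d", kind,
                         g$c0 * 1e3, g$ip3, i)
    cfg
  })
}

#' Simulate a population and collect ISI statistics
#'
#' Runs every configuration, detects spikes with [spike_stats_for_run()]
#' and returns one row per cell. Cells with fewer than `min_spikes`
#' detected spikes yield `NA` statistics (kept in the table, dropped from
#' regressions).
#'
#' @param configs list of [sim_config()]s (see [population_configs()]).
#' @param margin detection threshold margin above the resting level (µM).
#' @param min_separation debounce (s).
#' @param burn_in discarded initial transient (s).
#' @param min_spikes minimum spikes for a cell to contribute.
#' @param verbose print one line per cell.
#' @return data.frame with columns `label`, `n_spikes`, `T_av`, `sigma`,
#'   `n_isi`.
#' @export
run_isi_population <- function(configs, margin = 0.07, min_separation = 10,
                               burn_in = 40, min_spikes = 4,
                               verbose = FALSE) {
  rows <- lapply(configs, function(cfg) {
    ts <- run_cell(cfg)
    ss <- spike_stats_for_run(ts, margin = margin,
                              min_separation = min_separation,
                              burn_in = burn_in)
    n <- length(ss$train)
    st <- if (n >= min_spikes) isi_stats(ss$train) else
      list(T_av = NA_real_, sigma = NA_real_, n_isi = NA_integer_)
    if (verbose) {
      message(sprintf("%s: %d spikes, T_av %.1f s, sigma %.1f s",
                      cfg$label %||% "cell", n, st$T_av, st$sigma))
    }
    data.frame(label = cfg$label %||% NA_character_, n_spikes = n,
               T_av = st$T_av, sigma = st$sigma, n_isi = st$n_isi)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sigma-T_av regression of a population table
#'
#' @param pop a table from [run_isi_population()].
#' @param ... passed to [sigma_tav_regression()].
#' @return regression result, or `NULL` if fewer than 3 cells spiked.
#' @export
population_regression <- function(pop, ...) {
  ok <- stats::complete.cases(pop[, c("T_av", "sigma")])
  if (sum(ok) < 3) return(NULL)
  sigma_tav_regression(pop[ok, ], ...)
}

#' Buffer-shift vectors of paired populations
#'
#' For each cell simulated before and after buffer loading, the shift
#' vector `(delta T_av, delta sigma)`; its slope is the paper-style
#' buffer-shift readout.
#'
#' @param pop_before,pop_after tables from [run_isi_population()] with
#'   matching cell order.
#' @return list with per-cell `dT`, `dsigma` and the mean shift slope
#'   `slope` (mean of `dsigma/dT` over cells with `dT > 0`).
#' @export
buffer_shift_slopes <- function(pop_before, pop_after) {
  stopifnot(nrow(pop_before) == nrow(pop_after))
  ok <- stats::complete.cases(pop_before$T_av, pop_after$T_av)
  dT <- pop_after$T_av[ok] - pop_before$T_av[ok]
  ds <- pop_after$sigma[ok] - pop_before$sigma[ok]
  use <- dT > 0
  list(dT = dT, dsigma = ds,
       slope = if (any(use)) mean(ds[use] / dT[use]) else NA_real_,
       n = sum(use))
}
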