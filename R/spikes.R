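# Spike detection and interspike-interval (ISI) statistics.
#
# The central readout of the simulated signals is the relation between the
# standard deviation and the mean of the ISIs: random spike generation by
# wave nucleation after a deterministic refractory period Delta gives
# sigma = T_av - Delta, i.e. a line of slope 1 whose crossing of the T_av
# axis is the refractory period. A surrogate generator (refractory offset
# plus exponential or gamma ISIs) ships here so the statistics tier can be
# exercised and tested without the simulator.

#' Detect spikes by threshold crossing
#'
#' A spike is registered at each upward crossing of `c_avg` through
#' `threshold`; subsequent crossings within `min_separation` are ignored
#' (debounce).
#'
#' @param trace a `ca_timeseries` or data.frame with columns `time` and
#'   `c_avg`, or a numeric vector of concentrations with `times` supplied.
#' @param threshold concentration threshold (µM); must exceed the resting
#'   level of the trace.
#' @param min_separation debounce time (s).
#' @param times sample times when `trace` is a bare numeric vector.
#' @param c0 resting level used for validation (µM).
#' @return An object of class `spike_train`: numeric vector of spike times.
#' @export
detect_spikes <- function(trace, threshold = 0.12, min_separation = 10,
                          times = NULL, c0 = 0.05) {
  if (is.data.frame(trace)) {
    times <- trace$time
    x <- trace$c_avg
  } else {
    x <- as.numeric(trace)
    if (is.null(times)) times <- seq_along(x)
  }
  if (threshold <= c0) {
    stop("spike threshold must lie above the resting concentration",
         call. = FALSE)
  }
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  spikes <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (times[i] - last >= min_separation) {
      spikes <- c(spikes, times[i])
      last <- times[i]
    }
  }
  spike_train(spikes)
}

#' Spike train constructor
#'
#' @param times strictly increasing spike times (s).
#' @param id optional source identifier.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, id = NULL) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  structure(times, id = id, class = "spike_train")
}

#' ISI moment statistics
#'
#' Mean and (n-1)-denominator standard deviation of the successive
#' differences of a spike train.
#'
#' @param train a [spike_train()] (or numeric vector of spike times) with
#'   at least 3 spikes.
#' @return list with `T_av` (s), `sigma` (s), `n_isi`.
#' @export
isi_stats <- function(train) {
  times <- as.numeric(train)
  if (length(times) < 3) {
    stop("need at least 3 spikes for ISI statistics", call. = FALSE)
  }
  isi <- diff(times)
  list(T_av = mean(isi), sigma = stats::sd(isi), n_isi = length(isi))
}

#' Regression of ISI standard deviation on ISI mean
#'
#' Ordinary least squares of `sigma` on `T_av` across cells. The intercept
#' is reported both in the `sigma` direction and as the crossing of the
#' `T_av` axis (`-intercept/slope`), the deterministic recovery time of
#' the random-wave-nucleation picture. Uncertainties by nonparametric
#' bootstrap over cells.
#'
#' @param points list of [isi_stats()] results (or a data.frame with
#'   columns `T_av`, `sigma`).
#' @param n_boot bootstrap resamples (0 disables).
#' @param seed seed for the bootstrap.
#' @return list with `slope`, `intercept` (sigma at T_av = 0),
#'   `T_offset` (s), `slope_se`, `T_offset_se`, `n`.
#' @export
sigma_tav_regression <- function(points, n_boot = 1000, seed = 1L) {
  df <- isi_points_df(points)
  if (nrow(df) < 3) {
    stop("need at least 3 (T_av, sigma) points", call. = FALSE)
  }
  if (stats::sd(df$T_av) < 1e-12) {
    stop("degenerate T_av spread: regression undefined", call. = FALSE)
  }
  fit <- stats::lm(sigma ~ T_av, data = df)
  co <- stats::coef(fit)
  res <- list(slope = unname(co[2]), intercept = unname(co[1]),
              T_offset = unname(-co[1] / co[2]),
              slope_se = suppressWarnings(summary(fit)$coefficients[2, 2]),
              T_offset_se = NA_real_, n = nrow(df))
  if (n_boot > 0) {
    set.seed(seed)
    bs <- replicate(n_boot, {
      i <- sample.int(nrow(df), replace = TRUE)
      if (stats::sd(df$T_av[i]) < 1e-12) return(c(NA, NA))
      cb <- stats::coef(stats::lm(sigma ~ T_av, data = df[i, ]))
      c(cb[2], -cb[1] / cb[2])
    })
    res$slope_se <- stats::sd(bs[1, ], na.rm = TRUE)
    res$T_offset_se <- stats::sd(bs[2, ], na.rm = TRUE)
  }
  res
}

isi_points_df <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("T_av", "sigma") %in% names(points)))
    return(points[, c("T_av", "sigma")])
  }
  do.call(rbind, lapply(points, function(p)
    data.frame(T_av = p$T_av, sigma = p$sigma)))
}

#' Per-condition population slopes
#'
#' One sigma-T_av regression per experimental condition across the cells
#' of that condition.
#'
#' @param groups named list; each element a list of [isi_stats()] results
#'   (or a data.frame) for one condition.
#' @param ... passed to [sigma_tav_regression()].
#' @return named list of regression results.
#' @export
population_slope <- function(groups, ...) {
  if (any(vapply(groups, function(g) nrow(isi_points_df(g)) < 3,
                 logical(1)))) {
    stop("every condition needs at least 3 cells", call. = FALSE)
  }
  lapply(groups, sigma_tav_regression, ...)
}

#' Surrogate spike trains: refractory period plus stochastic ISI
#'
#' Generates ISI sequences `Delta + X` with `X` exponential of mean `m`
#' (the Poissonian wave-nucleation picture) or gamma with shape `shape`
#' and the same mean (for regularity sweeps). As the ISI count grows the
#' sigma-T_av cloud of such trains approaches slope 1 with T_av-axis
#' offset `Delta`.
#'
#' @param n_isi ISIs per train.
#' @param delta deterministic refractory period (s).
#' @param mean_exp mean of the stochastic ISI part (s); vectorised, one
#'   train per element.
#' @param shape gamma shape; 1 is exponential.
#' @param seed seed.
#' @return list of [spike_train()]s.
#' @export
surrogate_trains <- function(n_isi, delta = 20, mean_exp = 30, shape = 1,
                             seed = 1L) {
  set.seed(seed)
  lapply(mean_exp, function(m) {
    x <- stats::rgamma(n_isi, shape = shape, scale = m / shape)
    spike_train(cumsum(c(0, delta + x)))
  })
}

#' Spike train and ISI statistics of a simulated cell
#'
#' Convenience wrapper for simulator output: drops the equilibration
#' transient, detects spikes at a threshold placed a fixed margin above
#' the cell's resting concentration, and (when at least 4 spikes remain)
#' computes ISI statistics.
#'
#' @param run a `ca_timeseries` from [run_cell()].
#' @param threshold detection threshold (µM); default `c0 + margin`.
#' @param margin threshold margin over the resting concentration (µM).
#' @param min_separation debounce (s).
#' @param burn_in initial transient to discard (s).
#' @return list with `train` (a [spike_train()]) and `stats`
#'   ([isi_stats()] or `NULL` when there are fewer than 4 spikes).
#' @export
spike_stats_for_run <- function(run, threshold = NULL, margin = 0.07,
                                min_separation = 10, burn_in = 30) {
  c0 <- attr(run, "config")$p$c0
  if (is.null(threshold)) threshold <- c0 + margin
  tr <- detect_spikes(run[run$time > burn_in, , drop = FALSE],
                      threshold = threshold,
                      min_separation = min_separation, c0 = c0)
  list(train = tr,
       stats = if (length(tr) >= 4) isi_stats(tr) else NULL)
}
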