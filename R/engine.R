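# Whole-cell event-loop simulation: configuration, the run wrapper around
# the compiled core, field-state replay and grid snapshots.

#' Simulation configuration
#'
#' Bundles physiology, layout (or layout-generation parameters), channel
#' kinetics, field truncation and run control into one validated object.
#'
#' @param p a [phys_params()].
#' @param layout a `cluster_layout`, or `NULL` to generate one from
#'   `n_clusters`/`channel_range` with the master seed.
#' @param kinetics a [dyk_params()].
#' @param n_clusters,channel_range,min_sep,max_nn layout generation
#'   parameters (used when `layout` is `NULL`).
#' @param l_max,n_max mode-table truncation.
#' @param t_end simulated time (s).
#' @param dt_record recording cadence (s).
#' @param env_refresh maximum interval between full local-environment
#'   refreshes (s); `0` refreshes at every stochastic event.
#' @param refresh_cap cap of the geometrically growing refresh interval
#'   while all sources are silent (s).
#' @param field_tol mode-field magnitude (µM) below which, with all
#'   clusters closed, the spatial field is treated as fully decayed.
#' @param seed master seed; all randomness (layout, initial states,
#'   gating) derives from it.
#' @param record_cluster_open record per-cluster open-channel counts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p = phys_params(), layout = NULL,
                       kinetics = ipr_astrocyte_params(),
                       n_clusters = 47, channel_range = c(4L, 16L),
                       min_sep = 1, max_nn = 7,
                       l_max = 14, n_max = 20,
                       t_end = 100, dt_record = 0.1,
                       env_refresh = 1e-3, refresh_cap = 0.05,
                       field_tol = 1e-4, seed = 1L,
                       record_cluster_open = FALSE) {
  stopifnot(t_end > 0, dt_record > 0, env_refresh >= 0, l_max >= 0,
            n_max >= 1)
  structure(list(p = p, layout = layout, kinetics = kinetics,
                 n_clusters = n_clusters, channel_range = channel_range,
                 min_sep = min_sep, max_nn = max_nn,
                 l_max = l_max, n_max = n_max, t_end = t_end,
                 dt_record = dt_record, env_refresh = env_refresh,
                 refresh_cap = refresh_cap, field_tol = field_tol,
                 seed = as.integer(seed),
                 record_cluster_open = record_cluster_open),
            class = "sim_config")
}

# pairwise geometric factors of the mode table for evaluation at cluster
# positions offset 10 nm radially outward (the closed-cluster convention);
# dimensions (j, s, m) flattened j-major, as the compiled core expects
geo_pair_array <- function(modes, layout, offset = 0.01) {
  pos <- layout$positions
  n_cl <- nrow(pos)
  m <- length(modes$k)
  r_src <- sqrt(rowSums(pos^2))
  eval_pos <- pos
  for (j in seq_len(n_cl)) {
    dir <- if (r_src[j] < 1e-12) c(0, 0, 1) else pos[j, ] / r_src[j]
    eval_pos[j, ] <- pos[j, ] + offset * dir
  }
  r_ev <- sqrt(rowSums(eval_pos^2))
  basis_src <- t(vapply(r_src, function(r) sph_bessel_by_mode(modes, r),
                        numeric(m)))
  basis_ev <- t(vapply(r_ev, function(r) sph_bessel_by_mode(modes, r),
                       numeric(m)))
  w <- (2 * modes$l + 1) / (4 * pi * modes$norm)
  geo <- numeric(n_cl * n_cl * m)
  idx <- 1
  for (j in seq_len(n_cl)) {
    for (s in seq_len(n_cl)) {
      cosg <- if (r_ev[j] < 1e-12 || r_src[s] < 1e-12) 1 else
        max(-1, min(1, sum(eval_pos[j, ] * pos[s, ]) / (r_ev[j] * r_src[s])))
      Pl <- legendre_values(modes$l_max, cosg)
      geo[idx:(idx + m - 1)] <-
        basis_ev[j, ] * basis_src[s, ] * Pl[modes$l + 1] * w
      idx <- idx + m
    }
  }
  geo
}

#' Run a whole-cell simulation
#'
#' The event loop alternates (i) evaluation of the local environment at
#' every cluster from the Green's-function field plus quasi-static self
#' terms, (ii) exact sampling of the next subunit transition under the
#' piecewise-constant environment, (iii) current/source-history updates at
#' channel open/close events, and (iv) closed-form advancing of the field
#' and ER average. Identical configurations give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param modes optional precomputed `mode_table` (built and cached
#'   otherwise).
#' @param verbose print a short run report.
#' @return An object of class `ca_timeseries`: a data.frame with columns
#'   `time`, `c_avg`, `E_avg`, `n_open`, `n_inhibited` (and per-cluster
#'   open counts when requested), with the event log, final state, layout
#'   and run manifest attached as attributes.
#' @export
run_cell <- function(config, modes = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p
  set.seed(config$seed)
  layout <- config$layout
  if (is.null(layout)) {
    layout <- generate_layout(config$n_clusters, config$channel_range,
                              config$min_sep, config$max_nn,
                              cell_shape(p$cell_radius),
                              seed = config$seed)
  }
  if (is.null(modes)) {
    modes <- mode_table_cached(p, config$l_max, config$n_max)
  }
  usys <- uniform_system(p)
  geo <- geo_pair_array(modes, layout)
  m <- length(modes$k)
  geomax <- apply(matrix(abs(geo), nrow = m), 1, max)
  s_pair <- static_pair_matrix(layout, p)

  # initial subunit states from the resting stationary distribution;
  # the layout generator already consumed part of the seed stream, so this
  # is reproducible as a whole
  set.seed(config$seed + 1L)
  pstat <- subunit_stationary(local_env(p$c0, p$ip3), config$kinetics)
  nsub <- 4 * sum(layout$channels)
  init_states <- sample(0:7, nsub, replace = TRUE, prob = pstat)

  lam_flat <- as.numeric(t(modes$lambda))   # mode-major triples
  res_flat <- as.numeric(t(modes$res_c))
  phys <- list(c0 = p$c0, E0 = p$E0, gamma = p$gamma,
               V_cell = 4 / 3 * pi * p$cell_radius^3, D_c = p$D_c,
               D_E = p$D_E, channel_flux = p$channel_flux,
               channel_radius = p$channel_radius)
  kin <- c(config$kinetics$a, config$kinetics$b)

  raw <- .run_engine(layout$channels, kin, p$ip3, phys,
                     lam_flat, res_flat, geo, geomax, as.numeric(t(s_pair)),
                     usys$V, usys$Vi, usys$lambda,
                     init_states, config$t_end, config$dt_record,
                     config$env_refresh, config$refresh_cap,
                     config$field_tol, config$record_cluster_open)

  ts <- data.frame(time = raw$time, c_avg = raw$c_avg, E_avg = raw$E_avg,
                   n_open = raw$n_open, n_inhibited = raw$n_inhibited)
  attr(ts, "events") <- as.data.frame(raw$events)
  attr(ts, "final") <- raw$final
  attr(ts, "layout") <- layout
  attr(ts, "modes_meta") <- list(l_max = modes$l_max, n_max = modes$n_max,
                                 det_resid = max(modes$det_resid))
  attr(ts, "config") <- config
  attr(ts, "manifest") <- run_manifest(config, layout, modes, raw)
  if (config$record_cluster_open) {
    attr(ts, "cluster_open") <- raw$cluster_open
  }
  class(ts) <- c("ca_timeseries", "data.frame")
  if (verbose) {
    message(sprintf(
      "run_cell: %d clusters, %d channels, %.0f s; %d events, %d refreshes",
      nrow(layout$positions), sum(layout$channels), config$t_end,
      as.integer(raw$n_events), as.integer(raw$n_refresh)))
  }
  ts
}

#' @export
print.ca_timeseries <- function(x, ...) {
  cat("ca_timeseries:", nrow(x), "samples over",
      format(max(x$time)), "s;",
      nrow(attr(x, "events")), "source events\n")
  cat("  c_avg range [uM]:", format(range(x$c_avg), digits = 4), "\n")
  invisible(x)
}

#' Reconstruct the field state of a finished run
#'
#' Maps the compiled core's final amplitudes back into a [field_state()]
#' so that [evaluate_field()] and [snapshot_grid()] can be applied.
#'
#' @param run a `ca_timeseries` from [run_cell()].
#' @param modes the mode table of the run (rebuilt from the cache if
#'   omitted).
#' @return A `field_state` at the run's end time.
#' @export
field_state_of_run <- function(run, modes = NULL) {
  config <- attr(run, "config")
  layout <- attr(run, "layout")
  final <- attr(run, "final")
  if (is.null(modes)) {
    modes <- mode_table_cached(config$p, config$l_max, config$n_max)
  }
  st <- field_state(layout, modes, config$p)
  m <- length(modes$k)
  n_cl <- nrow(layout$positions)
  a <- final$A
  dim(a) <- c(3, m, n_cl)
  st$A <- aperm(a, c(3, 2, 1))
  st$u <- final$u
  st$t <- final$t
  st
}

#' Source history of a finished run
#'
#' @param run a `ca_timeseries`.
#' @return a [source_history()] rebuilt from the event log.
#' @export
history_of_run <- function(run) {
  ev <- attr(run, "events")
  layout <- attr(run, "layout")
  h <- source_history(nrow(layout$positions))
  for (i in seq_len(nrow(ev))) {
    h <- history_add_event(h, ev$time[i], ev$cluster[i], ev$n_open[i],
                           ev$current[i])
  }
  h
}

#' Concentration snapshot on a regular grid
#'
#' Evaluates the free Ca2+ field on a regular Cartesian grid spanning the
#' cell's bounding cube; grid nodes outside the cell are `NA`.
#'
#' @param state a [field_state()].
#' @param resolution nodes per axis (>= 8).
#' @return list with `axis` (node coordinates, µm) and `c` (3D array, µM).
#' @export
snapshot_grid <- function(state, resolution = 16) {
  stopifnot(resolution >= 8)
  R <- state$p$cell_radius
  ax <- seq(-R, R, length.out = resolution)
  arr <- array(NA_real_, dim = rep(resolution, 3))
  for (ix in seq_len(resolution)) {
    for (iy in seq_len(resolution)) {
      for (iz in seq_len(resolution)) {
        pt <- c(ax[ix], ax[iy], ax[iz])
        if (sqrt(sum(pt^2)) < R) {
          arr[ix, iy, iz] <- evaluate_field(state, pt)[["c"]]
        }
      }
    }
  }
  list(axis = ax, c = arr)
}

#' Run manifest
#'
#' Everything needed to reproduce a run bit-for-bit: resolved parameters,
#' seed, truncation, convergence diagnostics, package version.
#'
#' @param config a [sim_config()].
#' @param layout the resolved layout.
#' @param modes the mode table used.
#' @param raw engine diagnostics (internal).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, layout, modes, raw = NULL) {
  structure(list(
    package_version = as.character(utils::packageVersion("caspike")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    phys = unclass(config$p),
    kinetics = unclass(config$kinetics)[c("a", "b")],
    truncation = list(l_max = modes$l_max, n_max = modes$n_max,
                      max_det_resid = max(modes$det_resid)),
    run = list(t_end = config$t_end, dt_record = config$dt_record,
               env_refresh = config$env_refresh,
               refresh_cap = config$refresh_cap,
               field_tol = config$field_tol),
    layout = list(n_clusters = nrow(layout$positions),
                  channels = layout$channels,
                  positions = unname(layout$positions)),
    diagnostics = if (!is.null(raw)) list(n_events = raw$n_events,
                                          n_refresh = raw$n_refresh)),
    class = "run_manifest")
}

#' Write a manifest as JSON
#'
#' @param manifest a `run_manifest`.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
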