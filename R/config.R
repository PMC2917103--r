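# Plain-text configuration, experiment presets and fixture generation.
#
# Configuration files are key = value lines with explicit unit suffixes
# (nM, uM, mM, nm, um, ms, s, pA, per_s); the parameter tables mix nM/µM
# and nm/µm, so silent unit bugs are the dominant risk and units are
# validated, not assumed. Unknown keys are rejected.

config_keys <- function() {
  # name -> c(kind); kinds: conc (->uM), length (->um), time (->s),
  # rate (per_s), diff (um2_per_s), current (pA), number, integer, string
  list(
    cell_radius = "length", channel_radius = "length",
    D_c = "diff", D_E = "diff", D_b = "diff",
    c0 = "conc", ip3 = "conc",
    pump_rate = "rate", leak_rate = "rate",
    single_channel_pA = "current",
    mobile_buffer = "string", mobile_buffer_total = "conc",
    mobile_kon = "number", mobile_koff = "rate",
    immobile_buffer_total = "conc",
    immobile_kon = "number", immobile_koff = "rate",
    E0 = "conc", gamma = "number",
    n_clusters = "integer", channel_min = "integer",
    channel_max = "integer", min_sep = "length", max_nn = "length",
    l_max = "integer", n_max = "integer",
    t_end = "time", dt_record = "time", env_refresh = "time",
    seed = "integer",
    spike_threshold = "conc", spike_min_separation = "time")
}

parse_config_value <- function(key, raw, kind) {
  raw <- trimws(raw)
  if (kind == "string") return(tolower(raw))
  m <- regmatches(raw, regexec("^([-+0-9.eE]+)\\s*([a-zA-Z_0-9/]*)$", raw))[[1]]
  if (length(m) < 2 || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop("cannot parse value for '", key, "': ", raw, call. = FALSE)
  }
  val <- as.numeric(m[2])
  unit <- m[3]
  conv <- switch(kind,
    conc = c(nM = 1e-3, uM = 1, mM = 1e3),
    length = c(nm = 1e-3, um = 1),
    time = c(ms = 1e-3, s = 1),
    rate = c(per_s = 1, `1/s` = 1),
    diff = c(um2_per_s = 1),
    current = c(pA = 1),
    integer = ,
    number = c(none = 1))
  if (unit == "") {
    if (kind %in% c("number", "integer")) return(val)
    stop("missing unit for '", key, "' (expected one of ",
         paste(names(conv), collapse = ", "), ")", call. = FALSE)
  }
  if (!unit %in% names(conv)) {
    stop("unit mismatch for '", key, "': got '", unit, "', expected one of ",
         paste(names(conv), collapse = ", "), call. = FALSE)
  }
  val * conv[[unit]]
}

#' Load a simulation configuration from a plain-text file
#'
#' Lines of the form `key = value [unit]`; `#` starts a comment. Every key
#' must be one of the documented configuration keys; all keys are optional
#' and default to the standard parameter set (an empty file gives the full
#' default configuration: c0 = 50 nM, IP3 = 0.1 µM, 10 µm cell, 50 µM
#' mobile and 30 µM immobile buffer, ...).
#'
#' @param path file path.
#' @param overrides named list applied after the file (same keys).
#' @return A [sim_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  keys <- config_keys()
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
      key <- trimws(kv[1])
      if (!key %in% names(keys)) {
        stop("unknown configuration key: '", key, "'", call. = FALSE)
      }
      vals[[key]] <- parse_config_value(key, kv[2], keys[[key]])
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(keys)) {
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    }
    v <- overrides[[key]]
    vals[[key]] <- if (is.character(v)) {
      parse_config_value(key, v, keys[[key]])
    } else v
  }
  config_from_values(vals)
}

config_from_values <- function(vals) {
  get <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  buf <- if (!is.null(vals$mobile_kon) || !is.null(vals$mobile_koff)) {
    list(kon = get("mobile_kon", 0.2), koff = get("mobile_koff", 0.4))
  } else {
    buffer_kinetics(get("mobile_buffer", "endogenous"))
  }
  p <- phys_params(
    cell_radius = get("cell_radius", 10),
    channel_radius = get("channel_radius", 0.008),
    D_c = get("D_c", 223), D_E = get("D_E", 40), D_b = get("D_b", 75),
    c0 = get("c0", 0.05), ip3 = get("ip3", 0.1),
    pump_rate = get("pump_rate", 8),
    leak_rate = vals$leak_rate,
    single_channel_pA = get("single_channel_pA", 0.12),
    B_m = get("mobile_buffer_total", 50),
    kon_m = buf$kon, koff_m = buf$koff,
    B_i = get("immobile_buffer_total", 30),
    kon_i = get("immobile_kon", 0.5), koff_i = get("immobile_koff", 5),
    E0 = get("E0", 700), gamma = get("gamma", 5))
  cfg <- sim_config(
    p = p,
    n_clusters = get("n_clusters", 47),
    channel_range = c(get("channel_min", 4L), get("channel_max", 16L)),
    min_sep = get("min_sep", 1), max_nn = get("max_nn", 7),
    l_max = get("l_max", 14), n_max = get("n_max", 20),
    t_end = get("t_end", 100), dt_record = get("dt_record", 0.1),
    env_refresh = get("env_refresh", 1e-3),
    seed = get("seed", 1L))
  cfg$spike_threshold <- get("spike_threshold", 0.12)
  cfg$spike_min_separation <- get("spike_min_separation", 10)
  cfg
}

#' Rebuild a configuration from a run manifest
#'
#' @param manifest a `run_manifest` (see [run_manifest()]).
#' @return A [sim_config()] with the layout pinned, reproducing the run.
#' @export
config_from_manifest <- function(manifest) {
  ph <- manifest$phys
  p <- phys_params(cell_radius = ph$cell_radius,
                   channel_radius = ph$channel_radius,
                   D_c = ph$D_c, D_E = ph$D_E, D_b = ph$D_b,
                   c0 = ph$c0, ip3 = ph$ip3, pump_rate = ph$pump_rate,
                   leak_rate = ph$leak_rate, channel_flux = ph$channel_flux,
                   single_channel_pA = ph$single_channel_pA,
                   B_m = ph$B_m, kon_m = ph$kon_m, koff_m = ph$koff_m,
                   B_i = ph$B_i, kon_i = ph$kon_i, koff_i = ph$koff_i,
                   E0 = ph$E0, gamma = ph$gamma)
  kin <- do.call(dyk_params, as.list(stats::setNames(
    c(manifest$kinetics$a, manifest$kinetics$b),
    c(paste0("a", 1:5), paste0("b", 1:5)))))
  layout <- cluster_layout(manifest$layout$positions,
                           manifest$layout$channels,
                           cell_shape(ph$cell_radius))
  sim_config(p = p, layout = layout, kinetics = kin,
             l_max = manifest$truncation$l_max,
             n_max = manifest$truncation$n_max,
             t_end = manifest$run$t_end, dt_record = manifest$run$dt_record,
             env_refresh = manifest$run$env_refresh,
             refresh_cap = manifest$run$refresh_cap,
             field_tol = manifest$run$field_tol,
             seed = manifest$seed)
}

#' Experiment presets
#'
#' Configuration families of the three simulation protocols:
#' `"concentration_grid"` (a 47-cluster cell family on a grid of resting
#' Ca2+ and IP3 concentrations), `"signal_variety"` (one cell under
#' parameter variants producing regular, irregular, bursting and plateau
#' signals via resting level and SERCA strength), and `"buffer_sweep"`
#' (mobile-buffer loading sweeps at single-channel currents of 0.12 pA
#' and, via a tenfold lumenal concentration, 1.2 pA). Buffer loading is
#' represented by raising the total mobile-buffer pool; see the methods
#' vignette for the single-mobile-buffer rationale.
#'
#' @param name preset name.
#' @param scale factor in (0, 1] multiplying run lengths and population
#'   sizes (grid subsampling) for scaled-down reproduction.
#' @param base_t_end full-scale run length (s).
#' @param seed master seed; member configs get consecutive seeds.
#' @return list of [sim_config()]s with a `label` field each.
#' @export
preset_experiment <- function(name = c("concentration_grid",
                                       "signal_variety", "buffer_sweep"),
                              scale = 1, base_t_end = 600, seed = 1L) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  t_end <- max(60, base_t_end * scale)
  mk <- function(label, i, overrides_p = list(), n_clusters = 47,
                 channel_range = c(4L, 16L)) {
    p <- do.call(phys_params, overrides_p)
    cfg <- sim_config(p = p, n_clusters = n_clusters,
                      channel_range = channel_range, t_end = t_end,
                      seed = seed + i)
    cfg$label <- label
    cfg
  }
  if (name == "concentration_grid") {
    grid <- expand.grid(c0 = c(0.03, 0.04, 0.05, 0.06),
                        ip3 = c(0.05, 0.1, 0.15, 0.2))
    keep <- unique(round(seq(1, nrow(grid), length.out =
                               max(3, ceiling(nrow(grid) * scale)))))
    grid <- grid[keep, , drop = FALSE]
    return(lapply(seq_len(nrow(grid)), function(i)
      mk(sprintf("c0=%gnM_ip3=%guM", grid$c0[i] * 1e3, grid$ip3[i]), i,
         list(c0 = grid$c0[i], ip3 = grid$ip3[i]),
         n_clusters = 47)))
  }
  if (name == "signal_variety") {
    variants <- list(
      regular = list(c0 = 0.06, ip3 = 0.12),
      irregular = list(c0 = 0.04, ip3 = 0.12),
      bursting = list(pump_rate = 4),
      plateau = list(pump_rate = 2))
    return(lapply(seq_along(variants), function(i)
      mk(names(variants)[i], i, variants[[i]], n_clusters = 47)))
  }
  # buffer_sweep: loading = added mobile buffer, two current families
  sweeps <- list(
    list(tag = "buffered_0.12pA", E0 = 700, pA = 0.12),
    list(tag = "buffered_1.2pA", E0 = 7000, pA = 1.2))
  dB <- seq(0, 90, by = 10)
  out <- list()
  i <- 0
  for (sw in sweeps) {
    keep <- unique(round(seq(1, length(dB), length.out =
                               max(2, ceiling(length(dB) * scale)))))
    for (B in 50 + dB[keep]) {
      i <- i + 1
      out[[i]] <- mk(sprintf("%s_B=%guM", sw$tag, B), i,
                     list(B_m = B, E0 = sw$E0, single_channel_pA = sw$pA),
                     n_clusters = 47)
    }
  }
  out
}

#' Generate deterministic synthetic input files
#'
#' @param kind `"layout"` (tabular cluster layout), `"trace"` (square-pulse
#'   time series), or `"spiketrain"` (one spike time per line).
#' @param path output file path.
#' @param params named list of kind-specific parameters: layout takes
#'   `n_clusters`, `channel_range`; trace takes `n_pulses`, `period`,
#'   `amplitude`, `dt`; spiketrain takes `n_isi`, `delta`, `mean_exp`.
#' @param seed seed.
#' @return the path, invisibly.
#' @export
generate_fixtures <- function(kind = c("layout", "trace", "spiketrain"),
                              path, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  get <- function(key, default) {
    if (!is.null(params[[key]])) params[[key]] else default
  }
  if (kind == "layout") {
    layout <- generate_layout(get("n_clusters", 8),
                              get("channel_range", c(4L, 16L)),
                              seed = seed)
    write_layout(layout, path)
  } else if (kind == "trace") {
    n <- get("n_pulses", 5); period <- get("period", 60)
    amp <- get("amplitude", 1); dt <- get("dt", 0.1)
    t <- seq(0, n * period, by = dt)
    x <- rep(0.05, length(t))
    for (i in seq_len(n)) {
      x[t >= (i - 1) * period + period / 3 &
          t < (i - 1) * period + period / 2] <- amp
    }
    utils::write.table(data.frame(time = t, c_avg = x), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    tr <- surrogate_trains(get("n_isi", 500), get("delta", 20),
                           get("mean_exp", 30), seed = seed)[[1]]
    writeLines(format(as.numeric(tr), digits = 10), path)
  }
  invisible(path)
}

#' Write / read a time series as tab-separated text
#'
#' @param ts a `ca_timeseries` or data.frame.
#' @param path file path.
#' @rdname timeseries_io
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(as.data.frame(ts), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname timeseries_io
#' @export
read_timeseries <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
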