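# Quasi-static cluster sources.
#
# A cluster of open channels is collapsed to one point source whose current
# follows from the stationary two-domain (ER + cytosol superimposed)
# diffusion problem around a spherical source of radius R(n): the current is
# proportional to the spatially averaged transmembrane concentration
# difference, with a prefactor that accounts for local lumenal depletion
# through the channel flux constant and both diffusion coefficients. The
# same stationary profile gives the Ca2+ concentration an open cluster
# imposes at its own location.

#' Cluster source radius
#'
#' Radius of the lumped source as a function of the number of open
#' channels: `R_s * sqrt(n)` (source membrane area proportional to the
#' open-channel count); 0 when the cluster is closed. The rule is isolated
#' here so it can be replaced.
#'
#' @param n_open number of open channels (>= 0).
#' @param R_s single-channel radius (µm).
#' @return radius (µm).
#' @export
cluster_radius <- function(n_open, R_s = 0.008) {
  stopifnot(all(n_open >= 0))
  ifelse(n_open == 0, 0, R_s * sqrt(n_open))
}

#' Quasi-static cluster current
#'
#' Current (µM µm³/s) of a cluster with `n_open` open channels at average
#' cytosolic and lumenal concentrations `c_avg`, `e_avg`:
#' \deqn{I = \frac{n k_1 (E - c)}{1 + n k_1 (1/D_E + 1/D_c) / (4\pi R(n))}}
#' The denominator is the local-depletion correction of the stationary
#' two-domain source problem; it makes the per-channel current drop as
#' clusters grow.
#'
#' @param n_open open channels.
#' @param c_avg average cytosolic free Ca2+ (µM).
#' @param e_avg average lumenal free Ca2+ (µM).
#' @param p a [phys_params()].
#' @return current amplitude (µM µm³/s); 0 for a closed cluster.
#' @export
cluster_current <- function(n_open, c_avg, e_avg, p) {
  if (c_avg < 0 || e_avg < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (n_open == 0) return(0)
  k1 <- p$channel_flux
  g <- 1 / p$D_E + 1 / p$D_c
  R <- cluster_radius(n_open, p$channel_radius)
  n_open * k1 * (e_avg - c_avg) / (1 + n_open * k1 * g / (4 * pi * R))
}

#' Cluster state descriptor
#'
#' @param index cluster index.
#' @param n_open open channels.
#' @param current current amplitude (µM µm³/s).
#' @param p a [phys_params()] (for the radius rule).
#' @return list with `index`, `n_open`, `radius`, `current`.
#' @export
cluster_state <- function(index, n_open, current, p) {
  if ((n_open == 0) != (current == 0)) {
    stop("current must be zero exactly when the cluster is closed",
         call. = FALSE)
  }
  list(index = index, n_open = n_open,
       radius = cluster_radius(n_open, p$channel_radius), current = current)
}

#' Self-induced concentration at an open cluster
#'
#' Stationary near-field of the cluster's own current at the source
#' surface, `I / (4 pi D_c R(n))`; buffer uptake is negligible at
#' distances far below the diffusion length, so the free-diffusion profile
#' applies. Linear in the current.
#'
#' @param cl a [cluster_state()] with `n_open >= 1`.
#' @param p a [phys_params()].
#' @return concentration contribution (µM).
#' @export
local_open_concentration <- function(cl, p) {
  if (cl$n_open < 1) {
    stop("local_open_concentration is defined for open clusters only",
         call. = FALSE)
  }
  cl$current / (4 * pi * p$D_c * cl$radius)
}

#' Local environment seen by the channels of a cluster
#'
#' Open cluster: quasi-static self term plus the Green's-function field of
#' all other clusters at the cluster position. Closed cluster: the full
#' field (own history included) evaluated 10 nm radially outward from the
#' release site. Both include the resting level and the uniform deviation.
#'
#' @param k cluster index.
#' @param state a [field_state()] advanced to the evaluation time.
#' @param history a [source_history()] (to read the cluster's current).
#' @param p a [phys_params()].
#' @param offset evaluation offset for closed clusters (µm, default 10 nm).
#' @return a [local_env()].
#' @export
local_env_at_cluster <- function(k, state, history, p, offset = 0.01) {
  pos <- state$layout$positions[k, ]
  tt <- history$time[[k]]
  i <- if (length(tt)) findInterval(state$t, tt) else 0L
  cur <- if (i == 0) 0 else history$current[[k]][i]
  n_open <- if (i == 0) 0L else history$n_open[[k]][i]
  if (n_open >= 1) {
    cl <- cluster_state(k, n_open, cur, p)
    f <- evaluate_field(state, pos, exclude_source = k)
    cc <- f[["c"]] + local_open_concentration(cl, p)
  } else {
    r <- sqrt(sum(pos^2))
    dir <- if (r < 1e-12) c(0, 0, 1) else pos / r
    f <- evaluate_field(state, pos + offset * dir)
    cc <- f[["c"]]
  }
  local_env(max(cc, 0), p$ip3)
}
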