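# Spatial eigenmodes and temporal decay rates of the linearized
# three-species cytosolic field in a spherical cell.
#
# With a no-flux plasma membrane, the Laplacian eigenfunctions are
# j_l(k_ln r) Y_lm, with k_ln R a positive root of j_l'(x) = 0. For every
# spatial mode the linearized reactions couple (Ca2+, mobile buffer,
# immobile buffer) through a 3x3 matrix whose eigenvalues are the three
# temporal decay rates of the mode and whose eigenvectors give the residue
# weights of the Green's function. The uniform (k = 0) component carries
# the volume averages and the ER coupling and is handled separately
# (see uniform_system()).

#' Spherical Bessel function of the first kind
#'
#' @param l non-negative integer order.
#' @param x non-negative numeric vector.
#' @return `j_l(x)`.
#' @export
sph_bessel_j <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  if (any(small)) {
    # series limit x^l / (2l+1)!!
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- x[small]^l / dfact * (1 - x[small]^2 / (2 * (2 * l + 3)))
  }
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  }
  out
}

# derivative j_l'(x); l = 0 uses -j_1, otherwise the standard recurrence
sph_bessel_j_deriv <- function(l, x) {
  if (l == 0) return(-sph_bessel_j(1, x))
  sph_bessel_j(l - 1, x) - (l + 1) / x * sph_bessel_j(l, x)
}

# first n positive roots of j_l'(x) = 0 (no-flux radial eigenvalues)
neumann_radial_roots <- function(l, n) {
  roots <- numeric(0)
  x0 <- if (l == 0) 2 else max(0.5, 0.6 * l)
  x <- x0
  step <- 0.05
  g_prev <- sph_bessel_j_deriv(l, x)
  while (length(roots) < n) {
    x_new <- x + step
    g_new <- sph_bessel_j_deriv(l, x_new)
    if (is.finite(g_prev) && is.finite(g_new) && g_prev * g_new < 0) {
      r <- stats::uniroot(function(z) sph_bessel_j_deriv(l, z),
                          c(x, x_new), tol = 1e-13)$root
      roots <- c(roots, r)
    }
    x <- x_new
    g_prev <- g_new
    if (x > x0 + 20 + pi * (n + l + 5)) {
      stop("failed to locate ", n, " radial roots for l = ", l, call. = FALSE)
    }
  }
  roots
}

# 3x3 coupling matrix of the linearized (c, b, h) system at squared spatial
# frequency k2; rows/cols ordered (Ca2+, mobile buffer, immobile buffer)
coupling_matrix <- function(k2, p) {
  lr <- linearized_rates(p)
  matrix(c(
    -p$D_c * k2 - lr$theta_b - lr$theta_h - p$pump_rate, -lr$phi_b, -lr$phi_h,
    -lr$theta_b, -p$D_b * k2 - lr$phi_b, 0,
    -lr$theta_h, 0, -lr$phi_h), 3, 3, byrow = TRUE)
}

#' Precompute the mode table of the Green's function
#'
#' For every angular order `l = 0..l_max` and radial index `n = 1..n_max`
#' the radial eigenvalue is found from the no-flux boundary condition at
#' the cell radius, the 3x3 coupling matrix of the linearized three-species
#' system is assembled, and its three (real, negative) temporal decay rates
#' and residue weights are stored together with the mode normalization.
#'
#' @param p a [phys_params()].
#' @param l_max maximum angular order.
#' @param n_max number of radial modes per angular order.
#' @return An object of class `mode_table` with vectors `l`, `x` (root of
#'   the boundary condition), `k` (µm⁻¹), `norm` (µm³), `boundary`
#'   (radial basis value at the membrane), and `m x 3` matrices `lambda`
#'   (1/s), `res_c`, `res_b` (residues for the Ca2+ and mobile-buffer
#'   components of a Ca2+ point source).
#' @export
compute_modes <- function(p, l_max = 30, n_max = 60) {
  stopifnot(l_max >= 0, n_max >= 1)
  R <- p$cell_radius
  ls <- integer(0); xs <- numeric(0)
  for (l in 0:l_max) {
    r <- neumann_radial_roots(l, n_max)
    ls <- c(ls, rep.int(l, n_max))
    xs <- c(xs, r)
  }
  m <- length(xs)
  k <- xs / R
  jb <- vapply(seq_len(m), function(i) sph_bessel_j(ls[i], xs[i]), numeric(1))
  norm <- R^3 / 2 * (1 - ls * (ls + 1) / xs^2) * jb^2
  lambda <- matrix(NA_real_, m, 3)
  res_c <- matrix(NA_real_, m, 3)
  res_b <- matrix(NA_real_, m, 3)
  det_resid <- numeric(m)
  for (i in seq_len(m)) {
    M <- coupling_matrix(k[i]^2, p)
    eg <- eigen(M)
    if (max(abs(Im(eg$values))) > 1e-9 * max(abs(eg$values))) {
      stop("complex temporal rates for mode l=", ls[i], " k=", k[i],
           "; coupling matrix not sign-symmetric?", call. = FALSE)
    }
    lam <- Re(eg$values)
    V <- Re(eg$vectors)
    Vi <- solve(V)
    ord <- order(lam, decreasing = TRUE)  # slowest first
    lam <- lam[ord]; V <- V[, ord, drop = FALSE]; Vi <- Vi[ord, , drop = FALSE]
    lambda[i, ] <- lam
    # residues of a unit point source entering the Ca2+ equation
    res_c[i, ] <- V[1, ] * Vi[, 1]
    res_b[i, ] <- V[2, ] * Vi[, 1]
    det_resid[i] <- max(vapply(lam, function(z)
      abs(det(M - z * diag(3))), numeric(1))) /
      max(abs(lam))^3
  }
  if (any(lambda >= 0)) {
    stop("unstable temporal rate encountered; linear system should decay",
         call. = FALSE)
  }
  structure(list(l = ls, x = xs, k = k, norm = norm, boundary = jb,
                 lambda = lambda, res_c = res_c, res_b = res_b,
                 det_resid = det_resid, l_max = l_max, n_max = n_max,
                 cell_radius = R),
            class = "mode_table")
}

#' @export
print.mode_table <- function(x, ...) {
  cat("mode_table: l_max", x$l_max, ", n_max", x$n_max, "(",
      length(x$k), "modes ), max |det| residual",
      format(max(x$det_resid), digits = 3), "\n")
  invisible(x)
}

#' Build or load a cached mode table
#'
#' Mode tables depend only on the scaled parameters and the truncation;
#' they are cached on disk keyed by a hash of both.
#'
#' @inheritParams compute_modes
#' @param cache_dir directory for cached tables; default `tempdir()`.
#' @param verbose log cache hits/misses.
#' @return A `mode_table`.
#' @export
mode_table_cached <- function(p, l_max = 30, n_max = 60,
                              cache_dir = file.path(tempdir(), "caspike-modes"),
                              verbose = FALSE) {
  s <- nondimensionalize(p)
  key_src <- paste(c(vapply(s[sort(names(s))], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    l_max, n_max), collapse = "|")
  key <- sprintf("modes-%s.rds", substr(digest_string(key_src), 1, 16))
  path <- file.path(cache_dir, key)
  if (file.exists(path)) {
    if (verbose) message("mode table cache hit: ", path)
    return(readRDS(path))
  }
  if (verbose) message("mode table cache miss; computing ", l_max, "x", n_max)
  mt <- compute_modes(p, l_max, n_max)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(mt, path)
  mt
}

# small dependency-free string hash (two polynomial hashes mod a prime)
digest_string <- function(s) {
  bytes <- utf8ToInt(s)
  p <- 2147483647
  h <- 17; h2 <- 19
  for (b in bytes) h <- (h * 31 + b) %% p
  for (b in rev(bytes)) h2 <- (h2 * 37 + b) %% p
  sprintf("%08x%08x", as.integer(h), as.integer(h2))
}

#' Mode-truncation convergence check
#'
#' Compares the single-source field (static split plus transient mode
#' remainder) of a truncation against a doubled truncation at a set of
#' probe distances and times after switch-on, and reports the maximum
#' relative change. The static part is analytic, so only the transient
#' remainder depends on the truncation; probing shortly after switch-on
#' is the worst case.
#'
#' @param p a [phys_params()].
#' @param l_max,n_max candidate truncation.
#' @param distances probe distances from the source (µm).
#' @param times probe times after switch-on (s).
#' @param current source amplitude (µM µm³/s) used in the probe.
#' @return list with `max_rel_change` and the probed fields.
#' @export
mode_convergence_check <- function(p, l_max, n_max,
                                   distances = c(1, 2, 4),
                                   times = c(0.05, 0.2, 1),
                                   current = pA_to_flux(0.12) * 4) {
  f1 <- transient_probe_field(p, l_max, n_max, distances, times, current)
  f2 <- transient_probe_field(p, 2 * l_max, 2 * n_max, distances, times,
                              current)
  list(max_rel_change = max(abs(f2 - f1) / pmax(abs(f2), 1e-4)),
       field = f1, field_refined = f2, distances = distances,
       times = times)
}

# switch-on anomaly of a point source at half radius, probed along the
# axis towards the centre
transient_probe_field <- function(p, l_max, n_max, distances, times,
                                  current) {
  mt <- compute_modes(p, l_max, n_max)
  src <- c(0, 0, p$cell_radius / 2)
  layout <- cluster_layout(matrix(src, 1, 3), 1L)
  st0 <- field_state(layout, mt, p)
  out <- matrix(NA_real_, length(times), length(distances))
  for (i in seq_along(times)) {
    st <- advance_field(st0, times[i], current)
    out[i, ] <- vapply(distances, function(d)
      evaluate_field(st, c(0, 0, p$cell_radius / 2 - d))[["c"]] -
        average_concentrations(st)[["c_avg"]], numeric(1))
  }
  out
}

# geometric factor of every mode for a (source, point) pair:
# j_l(k r_src) j_l(k r_pt) P_l(cos gamma) (2l+1) / (4 pi N)
mode_geometry <- function(mt, src, pt) {
  r_s <- sqrt(sum(src^2)); r_p <- sqrt(sum(pt^2))
  cosg <- if (r_s < 1e-12 || r_p < 1e-12) 1 else
    sum(src * pt) / (r_s * r_p)
  cosg <- max(-1, min(1, cosg))
  Pl <- legendre_values(mt$l_max, cosg)
  sph_bessel_by_mode(mt, r_s) * sph_bessel_by_mode(mt, r_p) *
    Pl[mt$l + 1] * (2 * mt$l + 1) / (4 * pi * mt$norm)
}

# j_l(k r) for every mode in the table at a single radius
sph_bessel_by_mode <- function(mt, r) {
  out <- numeric(length(mt$k))
  for (l in unique(mt$l)) {
    sel <- mt$l == l
    out[sel] <- sph_bessel_j(l, mt$k[sel] * r)
  }
  out
}

# P_0..P_lmax at scalar x by upward recurrence
legendre_values <- function(l_max, x) {
  P <- numeric(l_max + 1)
  P[1] <- 1
  if (l_max >= 1) P[2] <- x
  if (l_max >= 2) {
    for (l in 1:(l_max - 1)) {
      P[l + 2] <- ((2 * l + 1) * x * P[l + 1] - l * P[l]) / (l + 1)
    }
  }
  P
}
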