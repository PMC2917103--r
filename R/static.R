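# Quasi-static split of the Green's function.
#
# The time-dependent field of a piecewise-constant source is written as
# (static response to the instantaneous current) + (transient remainder).
# The static response of the linearized (c, b) system to a unit point
# current is a sum of two screened Coulomb kernels
#   S(d) = sum_q w_q exp(-kappa_q d) / (4 pi d),
# with kappa_q^2 the roots of the static determinant (the immobile buffer
# drops out of the stationary balance), plus a smooth correction enforcing
# the no-flux membrane, plus the uniform offset 1/(pump V). The transient
# remainder lives on the eigenmodes and decays mode by mode, so it only
# needs the low-order modes the smooth part of the dynamics actually
# excites -- this is what makes the eigenmode expansion tractable.

#' Static screened kernel of the linearized two-species system
#'
#' @param p a [phys_params()].
#' @return list with screening constants `kappa` (1/µm), kernel weights
#'   `wc`, `wb` (Ca2+ and mobile-buffer components, s/µm per current), and
#'   the uniform average `avg_gain` = 1/(pump_rate * V_cell) (s/µm³).
#' @export
static_kernel <- function(p) {
  lr <- linearized_rates(p)
  alpha <- lr$theta_b + p$pump_rate
  # roots z = kappa^2 of Dc Db z^2 - (Dc phi_b + Db alpha) z + phi_b pump
  A <- p$D_c * p$D_b
  B <- p$D_c * lr$phi_b + p$D_b * alpha
  C <- lr$phi_b * p$pump_rate
  disc <- sqrt(B^2 - 4 * A * C)
  z <- c((B - disc) / (2 * A), (B + disc) / (2 * A))
  kappa <- sqrt(z)
  wc <- c((-p$D_b * z[1] + lr$phi_b) / (A * (z[2] - z[1])),
          (-p$D_b * z[2] + lr$phi_b) / (A * (z[1] - z[2])))
  wb <- c(-lr$theta_b / (A * (z[2] - z[1])),
          -lr$theta_b / (A * (z[1] - z[2])))
  V <- 4 / 3 * pi * p$cell_radius^3
  list(kappa = kappa, wc = wc, wb = wb,
       avg_gain = 1 / (p$pump_rate * V),
       avg_gain_b = -lr$theta_b / lr$phi_b / (p$pump_rate * V), V_cell = V)
}

# modified spherical Bessel functions i_l, k_l and radial derivatives
sph_bessel_i <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-8
  if (any(small)) {
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- x[small]^l / dfact
  }
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselI(xs, l + 0.5)
  }
  out
}
sph_bessel_k <- function(l, x) sqrt(pi / (2 * x)) * besselK(x, l + 0.5)
sph_bessel_i_deriv <- function(l, x) {
  if (l == 0) return(sph_bessel_i(1, x))
  sph_bessel_i(l - 1, x) - (l + 1) / x * sph_bessel_i(l, x)
}
sph_bessel_k_deriv <- function(l, x) {
  km1 <- sph_bessel_k(if (l == 0) 0 else l - 1, x)  # k_{-1} = k_0
  -km1 - (l + 1) / x * sph_bessel_k(l, x)
}

#' Membrane-correction coefficients of the static kernel
#'
#' For a source at radius `r_s`, coefficients `c[l, q]` of the regular
#' solutions `i_l(kappa_q r)` that cancel the free kernel's flux through
#' the membrane, making the static field satisfy the no-flux condition for
#' both diffusing species.
#'
#' @param kern a [static_kernel()].
#' @param r_s source radius (µm).
#' @param R cell radius (µm).
#' @param l_max truncation of the correction series.
#' @return (l_max + 1) x 2 matrix of coefficients.
#' @keywords internal
static_corr_coefs <- function(kern, r_s, R, l_max = 40) {
  co <- matrix(0, l_max + 1, 2)
  W <- rbind(kern$wc, kern$wb)      # 2 x 2: component x root
  for (l in 0:l_max) {
    Amat <- matrix(0, 2, 2)
    rhs <- numeric(2)
    for (q in 1:2) {
      kq <- kern$kappa[q]
      ilp <- sph_bessel_i_deriv(l, kq * R)
      klp <- sph_bessel_k_deriv(l, kq * R)
      il_s <- sph_bessel_i(l, kq * r_s)
      Amat[, q] <- W[, q] * kq * ilp
      # exp(-k d)/(4 pi d) = (k/(2 pi^2)) sum (2l+1) i_l(k r<) k_l(k r>) P_l
      rhs <- rhs - W[, q] * kq^2 * il_s * klp * (2 / pi)
    }
    # the two columns have vastly different scales at large l; scale them
    sc <- apply(abs(Amat), 2, max)
    ok <- which(sc > 0 & is.finite(sc))
    if (!length(ok) || !all(is.finite(rhs))) next
    As <- sweep(Amat[, ok, drop = FALSE], 2, sc[ok], "/")
    sol <- tryCatch(
      if (length(ok) == 2) solve(As, rhs) else qr.solve(As, rhs),
      error = function(e) rep(0, length(ok)))
    co[l + 1, ok] <- sol / sc[ok]
    co[l + 1, !is.finite(co[l + 1, ])] <- 0
  }
  co
}

#' Static field of unit point currents
#'
#' Evaluates the zero-average static response (free screened kernels plus
#' membrane correction minus the uniform gain) of a unit current at
#' `src` on a point `pt`.
#'
#' @param kern a [static_kernel()].
#' @param src,pt positions (µm).
#' @param R cell radius (µm).
#' @param coefs optional precomputed [static_corr_coefs()] for this source
#'   radius.
#' @param l_max correction truncation when `coefs` is missing.
#' @return named vector `c(c = , b = )`: field per unit current (s/µm³).
#' @export
static_pair_field <- function(kern, src, pt, R, coefs = NULL, l_max = 40) {
  r_s <- sqrt(sum(src^2)); r_p <- sqrt(sum(pt^2))
  if (is.null(coefs)) coefs <- static_corr_coefs(kern, r_s, R, l_max)
  l_max <- nrow(coefs) - 1
  d <- sqrt(sum((pt - src)^2))
  free_c <- sum(kern$wc * exp(-kern$kappa * d)) / (4 * pi * d)
  free_b <- sum(kern$wb * exp(-kern$kappa * d)) / (4 * pi * d)
  cosg <- if (r_s < 1e-12 || r_p < 1e-12) 1 else
    max(-1, min(1, sum(src * pt) / (r_s * r_p)))
  Pl <- legendre_values(l_max, cosg)
  corr_c <- 0; corr_b <- 0
  for (q in 1:2) {
    il <- vapply(0:l_max, function(l)
      sph_bessel_i(l, kern$kappa[q] * r_p), numeric(1))
    s <- sum((2 * (0:l_max) + 1) / (4 * pi) * Pl * coefs[, q] * il)
    corr_c <- corr_c + kern$wc[q] * s
    corr_b <- corr_b + kern$wb[q] * s
  }
  c(c = free_c + corr_c - kern$avg_gain,
    b = free_b + corr_b - kern$avg_gain_b)
}

#' Static pair-gain matrix of a layout
#'
#' `S[j, s]` is the zero-average static Ca2+ response at cluster `j`'s
#' evaluation point (10 nm radially outward of its position, the
#' closed-cluster convention) to a unit current at cluster `s`.
#'
#' @param layout a `cluster_layout`.
#' @param p a [phys_params()].
#' @param offset evaluation offset (µm).
#' @param l_max membrane-correction truncation.
#' @return n x n matrix (s/µm³).
#' @export
static_pair_matrix <- function(layout, p, offset = 0.01, l_max = 40) {
  kern <- static_kernel(p)
  pos <- layout$positions
  n_cl <- nrow(pos)
  r_src <- sqrt(rowSums(pos^2))
  R <- p$cell_radius
  S <- matrix(0, n_cl, n_cl)
  coefs <- lapply(r_src, function(r) static_corr_coefs(kern, r, R, l_max))
  for (j in seq_len(n_cl)) {
    dir <- if (r_src[j] < 1e-12) c(0, 0, 1) else pos[j, ] / r_src[j]
    pt <- pos[j, ] + offset * dir
    for (s in seq_len(n_cl)) {
      S[j, s] <- static_pair_field(kern, pos[s, ], pt, R,
                                   coefs = coefs[[s]])[["c"]]
    }
  }
  S
}
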