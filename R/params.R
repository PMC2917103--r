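# Physiological parameters, linearization, nondimensionalization and leak
# calibration for the bi-domain cell model.
#
# Units at the interface are µM, µm, s and pA throughout. The cytosol hosts
# free Ca2+, one mobile buffer (EGTA or BAPTA kinetics) and one immobile
# buffer; the ER lumen is a single well-mixed average coupled through linear
# pump and leak fluxes and the stochastic channel currents.

#' Buffer kinetic presets
#'
#' Capture (1/(µM s)) and dissociation (1/s) rates for the two exogenous
#' mobile buffers used in experiments. EGTA is slow, BAPTA fast, at similar
#' affinity, which is what makes them differ in their effect on spatial
#' coupling.
#'
#' @param name `"egta"` or `"bapta"`.
#' @return list with `kon`, `koff`.
#' @export
buffer_kinetics <- function(name = c("endogenous", "egta", "bapta")) {
  switch(match.arg(name),
         endogenous = list(kon = 0.2, koff = 0.4),
         egta = list(kon = 1.5, koff = 0.3),
         bapta = list(kon = 600, koff = 100))
}

#' Physiological parameters of the cell model
#'
#' Defaults are the simulation standard set: a 10 µm cell, 8 nm channels,
#' resting cytosolic Ca2+ of 50 nM, 0.1 µM IP3, 50 µM mobile buffer with
#' EGTA kinetics and 30 µM immobile buffer. The channel flux constant is,
#' by default, calibrated so that one open channel at the resting
#' transmembrane concentration difference carries `single_channel_pA`
#' (0.12 pA); the tenfold current used in high-coupling simulations is
#' obtained by a tenfold lumenal concentration.
#'
#' @param cell_radius cell radius (µm).
#' @param channel_radius single-channel source radius (µm).
#' @param D_c,D_E,D_b diffusion coefficients of cytosolic Ca2+, lumenal
#'   Ca2+ and the mobile buffer (µm²/s).
#' @param c0 resting cytosolic free Ca2+ (µM).
#' @param ip3 IP3 concentration (µM), spatially uniform.
#' @param pump_rate linearized SERCA pump rate constant (1/s).
#' @param leak_rate ER leak flux constant (1/s, acts on the lumenal
#'   average); `NULL` means calibrated via [calibrate_leak()] so that the
#'   resting state is a fixed point.
#' @param channel_flux single-channel flux constant (µm³/s); `NULL` means
#'   calibrated from `single_channel_pA`.
#' @param single_channel_pA target single-channel current at rest (pA).
#' @param B_m,kon_m,koff_m total concentration (µM) and rates of the mobile
#'   buffer.
#' @param B_i,kon_i,koff_i total concentration (µM) and rates of the
#'   immobile buffer.
#' @param E0 equilibrium lumenal Ca2+ concentration (µM).
#' @param gamma cytosol/ER volume ratio (dimensionless).
#' @return An object of class `phys_params` with derived resting free
#'   buffer levels `b0`, `h0` and the calibrated constants filled in.
#' @export
phys_params <- function(cell_radius = 10, channel_radius = 0.008,
                        D_c = 223, D_E = 40, D_b = 75,
                        c0 = 0.05, ip3 = 0.1,
                        pump_rate = 8, leak_rate = NULL,
                        channel_flux = NULL, single_channel_pA = 0.12,
                        B_m = 50, kon_m = 0.2, koff_m = 0.4,
                        B_i = 30, kon_i = 0.5, koff_i = 5,
                        E0 = 700, gamma = 5) {
  p <- list(cell_radius = cell_radius, channel_radius = channel_radius,
            D_c = D_c, D_E = D_E, D_b = D_b, c0 = c0, ip3 = ip3,
            pump_rate = pump_rate, leak_rate = leak_rate,
            channel_flux = channel_flux,
            single_channel_pA = single_channel_pA,
            B_m = B_m, kon_m = kon_m, koff_m = koff_m,
            B_i = B_i, kon_i = kon_i, koff_i = koff_i,
            E0 = E0, gamma = gamma)
  num <- p[!vapply(p, is.null, logical(1))]
  if (any(!vapply(num, function(x) is.numeric(x) && is.finite(x), logical(1))) ||
      any(unlist(num) <= 0 & !names(unlist(num)) %in% c())) {
    bad <- names(num)[vapply(num, function(x) !is.numeric(x) || x <= 0,
                             logical(1))]
    if (length(bad)) {
      stop("phys_params must be positive finite numbers; offending: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  # resting free buffer levels from binding equilibrium at c0
  p$Kd_m <- koff_m / kon_m
  p$Kd_i <- koff_i / kon_i
  p$b0 <- B_m * p$Kd_m / (p$Kd_m + c0)
  p$h0 <- B_i * p$Kd_i / (p$Kd_i + c0)
  class(p) <- "phys_params"
  if (is.null(p$leak_rate)) p$leak_rate <- calibrate_leak(p)
  if (is.null(p$channel_flux)) {
    p$channel_flux <- calibrate_channel_flux(p, single_channel_pA)
  }
  p
}

#' @export
print.phys_params <- function(x, ...) {
  cat("phys_params: cell", x$cell_radius, "um | c0", x$c0 * 1e3, "nM | IP3",
      x$ip3, "uM | E0", x$E0, "uM\n")
  cat("  pump", x$pump_rate, "/s, leak", signif(x$leak_rate, 4),
      "/s, channel flux", signif(x$channel_flux, 4), "um^3/s (",
      signif(single_channel_current(x), 3), "pA )\n")
  cat("  mobile buffer", x$B_m, "uM (kon", x$kon_m, ", koff", x$koff_m,
      "), immobile", x$B_i, "uM\n")
  invisible(x)
}

# linearized reaction rates about the resting state (c0, b0, h0):
#   theta = kon * (free buffer at rest)   [Ca2+ loss rate into the buffer]
#   phi   = kon * c0 + koff               [buffer relaxation rate]
linearized_rates <- function(p) {
  list(theta_b = p$kon_m * p$b0, phi_b = p$kon_m * p$c0 + p$koff_m,
       theta_h = p$kon_i * p$h0, phi_h = p$kon_i * p$c0 + p$koff_i)
}

#' Calibrate the ER leak flux constant
#'
#' Returns the leak constant for which the homogeneous resting state
#' `(c0, b0, E0)` is an exact fixed point of the source-free dynamics:
#' leak influx `leak_rate * E0` balances pump efflux `pump_rate * c0`.
#'
#' @param p a [phys_params()].
#' @return leak flux constant (1/s).
#' @export
calibrate_leak <- function(p) {
  leak <- p$pump_rate * p$c0 / p$E0
  if (!is.finite(leak) || leak <= 0) {
    stop("no positive leak constant balances pump at rest", call. = FALSE)
  }
  leak
}

# 1 pA of Ca2+ (two charges) expressed as a concentration-volume flux
pA_to_flux <- function(pA) {
  # ions/s / Avogadro -> mol/s; 1 uM*um^3 = 1e-21 mol
  pA * 1e-12 / (2 * 1.602176634e-19) / 6.02214076e23 / 1e-21
}
flux_to_pA <- function(flux) flux / pA_to_flux(1)

# channel flux constant k1 such that a single open channel at the resting
# difference E0 - c0 carries the target current (quasi-static two-domain
# source, see cluster_current())
calibrate_channel_flux <- function(p, target_pA) {
  q <- pA_to_flux(target_pA)
  g <- 1 / p$D_E + 1 / p$D_c
  dC <- p$E0 - p$c0
  denom <- dC - q * g / (4 * pi * p$channel_radius)
  if (denom <= 0) {
    stop("target single-channel current unreachable: local depletion ",
         "saturates below ", target_pA, " pA at this E0", call. = FALSE)
  }
  q / denom
}

#' Actual single-channel current of a parameter set
#'
#' @param p a [phys_params()].
#' @return current of one open channel at the resting concentration
#'   difference, in pA.
#' @export
single_channel_current <- function(p) {
  flux_to_pA(cluster_current(1L, p$c0, p$E0, p))
}

#' Nondimensionalize physical parameters
#'
#' Scales time with the linearized mobile-buffer reaction time
#' `1 / (kon_m (c0 + b0) + koff_m)`, space with the corresponding diffusion
#' length of free Ca2+, and concentrations with the mobile-buffer
#' dissociation constant (Ca2+, ER) or the total buffer concentrations
#' (buffers). The mapping is exactly invertible via [redimensionalize()].
#'
#' @param p a [phys_params()].
#' @return An object of class `scaled_params` containing the dimensionless
#'   groups plus the scale factors needed for inversion.
#' @export
nondimensionalize <- function(p) {
  lr <- linearized_rates(p)
  rate_m <- p$kon_m * (p$c0 + p$b0) + p$koff_m
  t_scale <- 1 / rate_m
  x_scale <- sqrt(p$D_c * t_scale)
  if (!is.finite(t_scale) || t_scale <= 0 || x_scale <= 0) {
    stop("degenerate scales in nondimensionalization", call. = FALSE)
  }
  s <- list(
    t_scale = t_scale, x_scale = x_scale, c_scale = p$Kd_m,
    # dimensionless resting concentrations
    c0_hat = p$c0 / p$Kd_m, b0_hat = p$b0 / p$B_m, h0_hat = p$h0 / p$B_i,
    E0_hat = p$E0 / p$Kd_m,
    # transport and kinetic groups
    delta = p$D_b / p$D_c, delta_E = p$D_E / p$D_c,
    eps_m = t_scale * (p$kon_m * (p$c0 + p$b0) + p$koff_m),  # = 1 by design
    eps_i = t_scale * (p$kon_i * (p$c0 + p$h0) + p$koff_i),
    beta = (p$B_i / p$Kd_i) / (p$B_m / p$Kd_m),
    pump_hat = p$pump_rate * t_scale, leak_hat = p$leak_rate * t_scale,
    current_scale = p$Kd_m * x_scale^3 / t_scale,
    flux_hat = p$channel_flux * t_scale / x_scale^3,
    kappa = p$Kd_m / p$Kd_i,
    rho_cell = p$cell_radius / x_scale,
    rho_channel = p$channel_radius / x_scale,
    gamma = p$gamma, ip3_hat = p$ip3 / p$Kd_m,
    # totals kept for exact inversion
    B_m = p$B_m, B_i = p$B_i, kon_m = p$kon_m, kon_i = p$kon_i,
    single_channel_pA = p$single_channel_pA)
  class(s) <- "scaled_params"
  s
}

#' Reconstruct physical parameters from scaled ones
#'
#' @param s a `scaled_params` object from [nondimensionalize()].
#' @return A [phys_params()] equal to the original to machine precision.
#' @export
redimensionalize <- function(s) {
  Kd_m <- s$c_scale
  c0 <- s$c0_hat * Kd_m
  koff_m <- s$kon_m * Kd_m
  D_c <- s$x_scale^2 / s$t_scale
  Kd_i <- Kd_m / s$kappa
  koff_i <- s$kon_i * Kd_i
  phys_params(
    cell_radius = s$rho_cell * s$x_scale,
    channel_radius = s$rho_channel * s$x_scale,
    D_c = D_c, D_E = s$delta_E * D_c, D_b = s$delta * D_c,
    c0 = c0, ip3 = s$ip3_hat * Kd_m,
    pump_rate = s$pump_hat / s$t_scale,
    leak_rate = s$leak_hat / s$t_scale,
    channel_flux = s$flux_hat * s$x_scale^3 / s$t_scale,
    single_channel_pA = s$single_channel_pA,
    B_m = s$B_m, kon_m = s$kon_m, koff_m = koff_m,
    B_i = s$B_i, kon_i = s$kon_i, koff_i = koff_i,
    E0 = s$E0_hat * Kd_m, gamma = s$gamma)
}
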