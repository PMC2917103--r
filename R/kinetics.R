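# DeYoung-Keizer IP3 receptor subunit/channel kinetics.
#
# Each IP3R subunit carries three binding sites: IP3, activating Ca2+ and
# inhibiting Ca2+. Its state is a vertex (i, j, k) of the binary cube, where
# i = 1 if IP3 is bound, j = 1 if Ca2+ occupies the activating site and
# k = 1 if Ca2+ occupies the inhibiting site. The subunit is active in state
# (1, 1, 0) and a tetrameric channel conducts when at least three of its four
# subunits are active.

#' DeYoung-Keizer kinetic parameters
#'
#' Binding rate constants `a1..a5` (per µM per s) and dissociation rates
#' `b1..b5` (per s) of the subunit cube. `a1`/`b1` govern IP3 binding while
#' the inhibiting site is empty, `a3`/`b3` IP3 binding while it is occupied;
#' `a2`/`b2` govern inhibitory Ca2+ binding with IP3 bound, `a4`/`b4` without;
#' `a5`/`b5` govern the activating Ca2+ site. Defaults are the published
#' DeYoung-Keizer values, for which the dissociation constants satisfy
#' d1*d2 = d3*d4 so the cube obeys detailed balance.
#'
#' @param a1,a2,a3,a4,a5 binding rate constants (1/(µM s)).
#' @param b1,b2,b3,b4,b5 dissociation rates (1/s).
#' @return An object of class `dyk_params`.
#' @export
dyk_params <- function(a1 = 400, a2 = 0.2, a3 = 400, a4 = 0.2, a5 = 20,
                       b1 = 52, b2 = 0.2098, b3 = 377.36, b4 = 0.0289,
                       b5 = 1.6468) {
  k <- list(a = c(a1, a2, a3, a4, a5), b = c(b1, b2, b3, b4, b5))
  if (any(k$a <= 0) || any(k$b <= 0)) {
    stop("all DYK rate constants must be positive", call. = FALSE)
  }
  k$d <- k$b / k$a
  class(k) <- "dyk_params"
  k
}

#' @export
print.dyk_params <- function(x, ...) {
  cat("DeYoung-Keizer subunit kinetics\n")
  cat("  binding a1..a5 [1/(uM s)]:", format(x$a), "\n")
  cat("  unbinding b1..b5 [1/s]:   ", format(x$b), "\n")
  cat("  dissociation d1..d5 [uM]: ", format(x$d), "\n")
  invisible(x)
}

#' Local ligand environment of a channel
#'
#' @param c_local free Ca2+ concentration at the channel (µM).
#' @param ip3 IP3 concentration (µM); spatially uniform model parameter.
#' @return An object of class `local_env`.
#' @export
local_env <- function(c_local, ip3) {
  if (c_local < 0 || ip3 < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(list(c = c_local, ip3 = ip3), class = "local_env")
}

# subunit states are stored as integers 0..7 encoding i*4 + j*2 + k
subunit_index <- function(i, j, k) i * 4L + j * 2L + k
subunit_bits <- function(s) {
  cbind(i = s %/% 4L, j = (s %/% 2L) %% 2L, k = s %% 2L)
}

ACTIVE_STATE <- subunit_index(1L, 1L, 0L)  # (1,1,0)

#' Transition rates out of a subunit state
#'
#' Returns the three edges of the state cube leaving `state`, with their
#' rates. Binding rates are linear in the relevant ligand concentration,
#' unbinding rates are concentration independent.
#'
#' @param state integer vector `c(i, j, k)` of binary site occupancies.
#' @param env a [local_env()].
#' @param k a [dyk_params()].
#' @return Named numeric vector of length 3; names are the target states
#'   `"ijk"`.
#' @export
subunit_transition_rates <- function(state, env, k = dyk_params()) {
  stopifnot(length(state) == 3, all(state %in% c(0L, 1L)))
  i <- state[1]; j <- state[2]; kk <- state[3]
  rates <- numeric(3)
  to <- character(3)
  # IP3 site: a1/b1 while the inhibiting site is empty, a3/b3 otherwise
  rates[1] <- if (i == 0) {
    (if (kk == 0) k$a[1] else k$a[3]) * env$ip3
  } else {
    if (kk == 0) k$b[1] else k$b[3]
  }
  to[1] <- paste0(1 - i, j, kk)
  # activating Ca2+ site: a5/b5, independent of the other sites
  rates[2] <- if (j == 0) k$a[5] * env$c else k$b[5]
  to[2] <- paste0(i, 1 - j, kk)
  # inhibiting Ca2+ site: a2/b2 with IP3 bound, a4/b4 without
  rates[3] <- if (kk == 0) {
    (if (i == 1) k$a[2] else k$a[4]) * env$c
  } else {
    if (i == 1) k$b[2] else k$b[4]
  }
  to[3] <- paste0(i, j, 1 - kk)
  names(rates) <- to
  rates
}

#' Generator matrix of the 8-state subunit chain
#'
#' @inheritParams subunit_transition_rates
#' @return 8x8 matrix `Q` with `Q[s, s']` the rate from state `s` to `s'`
#'   (states ordered by index `i*4 + j*2 + k`, i.e. "000", "001", ...,
#'   "111"); rows sum to zero.
#' @export
subunit_generator <- function(env, k = dyk_params()) {
  Q <- matrix(0, 8, 8)
  bits <- subunit_bits(0:7)
  labels <- apply(bits, 1, paste0, collapse = "")
  rownames(Q) <- colnames(Q) <- labels
  for (s in 1:8) {
    r <- subunit_transition_rates(bits[s, ], env, k)
    Q[s, names(r)] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Is a channel open?
#'
#' A tetrameric channel conducts when at least three subunits are in the
#' active state (1,1,0).
#'
#' @param subunits integer matrix with 4 rows and columns (i, j, k), or an
#'   integer vector of 4 encoded states (`i*4 + j*2 + k`).
#' @return logical.
#' @export
channel_is_open <- function(subunits) {
  if (is.matrix(subunits)) {
    stopifnot(nrow(subunits) == 4)
    subunits <- subunit_index(subunits[, 1], subunits[, 2], subunits[, 3])
  }
  stopifnot(length(subunits) == 4)
  sum(subunits == ACTIVE_STATE) >= 3
}

# Closed-form stationary distribution of the subunit cube. Valid when the
# cycle condition d1*d2 = d3*d4 holds (detailed balance), which the default
# rates satisfy; otherwise fall back to solving pi %*% Q = 0 directly.
subunit_stationary <- function(env, k = dyk_params()) {
  balanced <- abs(k$d[1] * k$d[2] - k$d[3] * k$d[4]) <
    1e-9 * k$d[1] * k$d[2]
  if (balanced) {
    bits <- subunit_bits(0:7)
    # path 000 -> i00 -> i0k -> ijk; detailed balance makes this path-free
    w <- (env$ip3 / k$d[1])^bits[, "i"] *
      (env$c / k$d[5])^bits[, "j"] *
      ifelse(bits[, "i"] == 1, (env$c / k$d[2])^bits[, "k"],
             (env$c / k$d[4])^bits[, "k"])
    p <- w / sum(w)
  } else {
    Q <- subunit_generator(env, k)
    A <- rbind(t(Q), rep(1, 8))
    p <- qr.solve(A, c(rep(0, 8), 1))
  }
  names(p) <- apply(subunit_bits(0:7), 1, paste0, collapse = "")
  p
}

#' Stationary open probability of a channel
#'
#' Probability that a channel is open (at least 3 of 4 independent subunits
#' active) under fixed ligand concentrations, from the stationary
#' distribution of the subunit chain. Biphasic in `c` at fixed `ip3`:
#' activation by the high-affinity site raises it at low Ca2+, the
#' low-affinity inhibiting site pulls it down at high Ca2+.
#'
#' @param c free Ca2+ concentration (µM); vectorised.
#' @param ip3 IP3 concentration (µM).
#' @param k a [dyk_params()].
#' @return Open probability in `[0, 1]`, same length as `c`.
#' @export
stationary_open_probability <- function(c, ip3, k = dyk_params()) {
  vapply(c, function(cc) {
    p <- subunit_stationary(local_env(cc, ip3), k)
    pa <- p[["110"]]
    pa^4 + 4 * pa^3 * (1 - pa)
  }, numeric(1))
}

#' First transition of the channel ensemble under a time-varying environment
#'
#' Samples the first state transition of the inhomogeneous Markov process
#' whose propensities follow the deterministic local-concentration
#' trajectory `env_of_t`: a unit-mean exponential deviate is drawn and the
#' total propensity is integrated along the trajectory until the integral
#' reaches it. When the environment is constant this reduces to exact
#' (Gillespie) exponential sampling.
#'
#' @param channels list of channels; each channel is an integer vector of 4
#'   encoded subunit states (see [channel_is_open()]).
#' @param env_of_t function of time returning a [local_env()].
#' @param t0,horizon start and end of the sampling window (s).
#' @param k a [dyk_params()].
#' @param rel_tol relative tolerance of the propensity integration.
#' @return A list with `time`, `channel`, `subunit`, `new_state` (encoded)
#'   for the sampled transition, or `NULL` ("no event") if the integrated
#'   propensity over the window never reaches the drawn threshold.
#' @export
hybrid_next_event <- function(channels, env_of_t, t0, horizon,
                              k = dyk_params(), rel_tol = 1e-6) {
  stopifnot(horizon >= t0)
  target <- stats::rexp(1)

  total_propensity <- function(t) {
    env <- env_of_t(t)
    tot <- 0
    for (ch in channels) {
      b <- subunit_bits(ch)
      for (s in seq_len(nrow(b))) {
        tot <- tot + sum(subunit_transition_rates(b[s, ], env, k))
      }
    }
    tot
  }

  # accumulate the propensity integral on sub-intervals by adaptive Simpson
  cum <- 0
  t <- t0
  h <- max((horizon - t0) / 64, .Machine$double.eps)
  lam_t <- total_propensity(t)
  event_time <- NA_real_
  while (t < horizon) {
    h <- min(h, horizon - t)
    lam_m <- total_propensity(t + h / 2)
    lam_e <- total_propensity(t + h)
    seg <- h * (lam_t + 4 * lam_m + lam_e) / 6
    seg2 <- h * (lam_t + 4 * total_propensity(t + h / 4) +
                   2 * lam_m + 4 * total_propensity(t + 3 * h / 4) +
                   lam_e) / 12  # two-panel Simpson
    if (abs(seg2 - seg) > rel_tol * max(seg2, 1e-300) && h > 16 * .Machine$double.eps * max(1, abs(t))) {
      h <- h / 2
      next
    }
    if (cum + seg2 >= target) {
      # root of cumulative integral - target inside [t, t + h]
      f <- function(s) {
        stats::integrate(function(u) vapply(u, total_propensity, numeric(1)),
                         t, s, rel.tol = rel_tol)$value + cum - target
      }
      event_time <- stats::uniroot(f, c(t, t + h), tol = rel_tol * max(h, 1e-12))$root
      break
    }
    cum <- cum + seg2
    t <- t + h
    lam_t <- lam_e
    h <- h * 2
  }
  if (is.na(event_time)) return(NULL)

  # select the transition proportionally to propensities at the event time;
  # enumeration order (channel, subunit, edge) fixes tie-breaking
  env <- env_of_t(event_time)
  props <- list()
  tot <- 0
  for (ci in seq_along(channels)) {
    b <- subunit_bits(channels[[ci]])
    for (si in seq_len(nrow(b))) {
      r <- subunit_transition_rates(b[si, ], env, k)
      for (ei in seq_along(r)) {
        tot <- tot + r[ei]
        props[[length(props) + 1]] <- list(ci = ci, si = si,
                                           to = names(r)[ei], cum = tot)
      }
    }
  }
  if (tot <= 0) return(NULL)
  u <- stats::runif(1) * tot
  sel <- props[[which.max(vapply(props, function(p) p$cum >= u, logical(1)))]]
  bits <- as.integer(strsplit(sel$to, "")[[1]])
  list(time = event_time, channel = sel$ci, subunit = sel$si,
       new_state = subunit_index(bits[1], bits[2], bits[3]))
}

#' Astrocyte-adapted IP3R subunit kinetics
#'
#' The DeYoung-Keizer cube with rate constants adapted to the slow,
#' high-affinity IP3R2-dominated gating of astrocytes: tight and slow IP3
#' binding (`d1` = 0.02 µM), an activating Ca2+ site moved to the
#' bell-curve optimum scale (`d5` = 1 µM, giving maximal cooperative
#' modulation over the 0.05-0.5 µM range that inter-cluster coupling
#' spans), and slow Ca2+ inhibition (binding 0.05 per µM s) whose
#' unbinding rates (0.052 and 0.025 per s) set the tens-of-seconds
#' recovery that appears as the deterministic part of the interspike
#' interval. The cycle condition `d1 d2 = d3 d4` is preserved, so the
#' cube satisfies detailed balance.
#'
#' @param ... overrides forwarded to [dyk_params()].
#' @return A [dyk_params()] object.
#' @export
ipr_astrocyte_params <- function(...) {
  d1 <- 0.02; d2 <- 1.049; d4 <- 0.5
  d3 <- d1 * d2 / d4
  defaults <- list(a1 = 60, b1 = 60 * d1, a3 = 60, b3 = 60 * d3,
                   a5 = 15, b5 = 15, a2 = 0.05, b2 = 0.05 * d2,
                   a4 = 0.05, b4 = 0.05 * d4)
  args <- utils::modifyList(defaults, list(...))
  do.call(dyk_params, args)
}
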