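# Green's-function field state.
#
# The field of the piecewise-constant cluster currents is decomposed as
#   field(x, t) = rest + uniform(t) + sum_s I_s(t) * Stilde(x, x_s)
#                 + transient remainder,
# where Stilde is the zero-average static response to a unit current
# (static.R) and the remainder lives on the k > 0 eigenmodes: one amplitude
# per (cluster, mode, temporal root) that decays exponentially between
# events and jumps by -dI/|lambda| when a cluster current switches, so that
# the total field is continuous in time. High-k modes decay within
# microseconds and carry negligible remainder, which is what lets a modest
# mode truncation represent the dynamics once the singular static part is
# split off. The uniform (k = 0) component carries the volume averages and
# the ER coupling as an exact 4-variable linear ODE; with a no-flux
# membrane every k > 0 mode has zero volume integral, so total cell
# calcium (free + buffer-bound + ER/gamma) is conserved by construction.

#' Per-cluster piecewise-constant source history
#'
#' Ordered switch times and current amplitudes per cluster; the amplitude
#' changes only at channel open/close events.
#'
#' @param n_clusters number of clusters.
#' @return An object of class `source_history`.
#' @export
source_history <- function(n_clusters) {
  structure(list(time = vector("list", n_clusters),
                 current = vector("list", n_clusters),
                 n_open = vector("list", n_clusters),
                 n_clusters = n_clusters),
            class = "source_history")
}

#' Record a current switch
#'
#' @param history a [source_history()].
#' @param t switch time (s); must exceed the cluster's previous switch time.
#' @param cluster cluster index.
#' @param n_open open-channel count after the switch.
#' @param current new current amplitude (µM µm³/s).
#' @export
history_add_event <- function(history, t, cluster, n_open, current) {
  tt <- history$time[[cluster]]
  if (length(tt) && t <= tt[length(tt)]) {
    stop("switch times must be strictly increasing per cluster",
         call. = FALSE)
  }
  history$time[[cluster]] <- c(tt, t)
  history$current[[cluster]] <- c(history$current[[cluster]], current)
  history$n_open[[cluster]] <- c(history$n_open[[cluster]], n_open)
  history
}

#' Current amplitudes at a time point
#'
#' @param history a [source_history()].
#' @param t time (s).
#' @return numeric vector of per-cluster current amplitudes (µM µm³/s).
#' @export
history_currents_at <- function(history, t) {
  vapply(seq_len(history$n_clusters), function(k) {
    tt <- history$time[[k]]
    i <- findInterval(t, tt)
    if (i == 0) 0 else history$current[[k]][i]
  }, numeric(1))
}

#' Export a source history as a tabular event log
#'
#' @param history a [source_history()].
#' @return data.frame with columns time, cluster, n_open, current, sorted
#'   by time.
#' @export
history_as_events <- function(history) {
  df <- do.call(rbind, lapply(seq_len(history$n_clusters), function(k) {
    if (!length(history$time[[k]])) return(NULL)
    data.frame(time = history$time[[k]], cluster = k,
               n_open = history$n_open[[k]], current = history$current[[k]])
  }))
  if (is.null(df)) {
    df <- data.frame(time = numeric(0), cluster = integer(0),
                     n_open = integer(0), current = numeric(0))
  }
  df[order(df$time), , drop = FALSE]
}

# 4x4 generator of the uniform component (deviations from rest):
# rows/cols (c_avg, b_avg, h_avg, E_avg)
uniform_matrix <- function(p) {
  lr <- linearized_rates(p)
  matrix(c(
    -lr$theta_b - lr$theta_h - p$pump_rate, -lr$phi_b, -lr$phi_h, p$leak_rate,
    -lr$theta_b, -lr$phi_b, 0, 0,
    -lr$theta_h, 0, -lr$phi_h, 0,
    p$gamma * p$pump_rate, 0, 0, -p$gamma * p$leak_rate),
    4, 4, byrow = TRUE)
}

#' Uniform-component propagator
#'
#' Eigendecomposition of the 4x4 uniform system used to advance the volume
#' averages exactly over source-constant intervals. One eigenvalue is zero:
#' the conserved total-calcium combination.
#'
#' @param p a [phys_params()].
#' @return list with `M`, eigenvalues `lambda` and (real) eigenvector
#'   matrices `V`, `Vi`.
#' @export
uniform_system <- function(p) {
  M <- uniform_matrix(p)
  eg <- eigen(M)
  if (max(abs(Im(eg$values))) > 1e-9 * max(abs(eg$values), 1)) {
    stop("uniform system has complex rates; unexpected for this coupling",
         call. = FALSE)
  }
  V <- Re(eg$vectors)
  list(M = M, lambda = Re(eg$values), V = V, Vi = solve(V))
}

# (exp(lambda dt) - 1)/lambda with the lambda -> 0 limit
phi_exp <- function(lambda, dt) {
  ifelse(abs(lambda * dt) < 1e-8,
         dt * (1 + lambda * dt / 2),
         expm1(lambda * dt) / lambda)
}

#' Initialise a field state
#'
#' @param layout a `cluster_layout`.
#' @param modes a `mode_table` (see [compute_modes()]).
#' @param p a [phys_params()].
#' @param l_corr truncation of the static membrane-correction series.
#' @return An object of class `field_state`: zero transient amplitudes,
#'   zero currents, resting averages, time 0.
#' @export
field_state <- function(layout, modes, p, l_corr = 40) {
  n_cl <- nrow(layout$positions)
  m <- length(modes$k)
  kern <- static_kernel(p)
  r_src <- sqrt(rowSums(layout$positions^2))
  structure(list(
    A = array(0, dim = c(n_cl, m, 3)),   # transient (remainder) amplitudes
    u = numeric(4),            # deviations (c, b, h, E) of the averages
    currents = numeric(n_cl),
    t = 0,
    layout = layout, modes = modes, p = p,
    kern = kern,
    corr = lapply(r_src, function(r)
      static_corr_coefs(kern, r, p$cell_radius, l_corr)),
    usys = uniform_system(p),
    V_cell = 4 / 3 * pi * p$cell_radius^3,
    src_basis = t(vapply(seq_len(n_cl), function(s)
      sph_bessel_by_mode(modes, r_src[s]), numeric(m)))),
    class = "field_state")
}

#' Switch the cluster currents of a field state
#'
#' Applies the transient-amplitude jumps `dI / lambda` that keep the total
#' field continuous when the static part switches to the new currents.
#' Must be called at the switch time (state advanced there first).
#'
#' @param state a [field_state()].
#' @param currents new per-cluster current amplitudes (µM µm³/s).
#' @return the updated state.
#' @export
field_apply_currents <- function(state, currents) {
  dI <- currents - state$currents
  for (s in which(dI != 0)) {
    state$A[s, , ] <- state$A[s, , ] + dI[s] / state$modes$lambda
  }
  state$currents <- currents
  state
}

#' Advance the field to a later time under constant currents
#'
#' Transient amplitudes decay exponentially; the uniform component is
#' advanced by its matrix exponential driven by the total current. Cost is
#' O(modes x clusters), independent of the history length.
#'
#' @param state a [field_state()].
#' @param t_new target time (s), `>= state$t`.
#' @param currents optional per-cluster currents in effect on the
#'   interval; if they differ from the state's, the switch is applied at
#'   the interval start via [field_apply_currents()].
#' @return The advanced `field_state`.
#' @export
advance_field <- function(state, t_new, currents = NULL) {
  if (!is.null(currents) && any(currents != state$currents)) {
    state <- field_apply_currents(state, currents)
  }
  dt <- t_new - state$t
  if (dt < 0) stop("cannot advance the field into the past", call. = FALSE)
  if (dt == 0) return(state)
  em <- exp(state$modes$lambda * dt)    # m x 3
  n_cl <- dim(state$A)[1]
  for (s in seq_len(n_cl)) {
    state$A[s, , ] <- em * state$A[s, , ]
  }
  J <- sum(state$currents) / state$V_cell
  f <- J * c(1, 0, 0, -state$p$gamma)
  us <- state$usys
  w <- us$Vi %*% state$u
  wf <- us$Vi %*% f
  state$u <- as.numeric(us$V %*% (exp(us$lambda * dt) * w +
                                    phi_exp(us$lambda, dt) * wf))
  state$t <- t_new
  state
}

#' Advance the field through a source history
#'
#' Walks the event boundaries of `history` between the state's time and
#' `t_new`, switching currents at each boundary.
#'
#' @param state a [field_state()].
#' @param history a [source_history()].
#' @param t_new target time (s).
#' @return the advanced state.
#' @export
advance_field_history <- function(state, history, t_new) {
  ev <- history_as_events(history)
  ev <- ev[ev$time > state$t & ev$time <= t_new, , drop = FALSE]
  state <- advance_field(state, state$t,
                         history_currents_at(history, state$t))
  for (i in seq_len(nrow(ev))) {
    state <- advance_field(state, ev$time[i])
    cur <- state$currents
    cur[ev$cluster[i]] <- ev$current[i]
    state <- field_apply_currents(state, cur)
  }
  advance_field(state, t_new)
}

#' Evaluate the concentration field at a point
#'
#' Resting offset plus uniform deviation plus, per source, the static
#' response to its instantaneous current and the mode sum of the transient
#' remainder (radial basis at the field point and at the source times the
#' Legendre polynomial of the enclosed angle times the per-root
#' amplitudes). Exactly additive over sources and history segments.
#'
#' @param state a [field_state()] advanced to the evaluation time.
#' @param point length-3 position (µm) strictly inside the cell.
#' @param exclude_source optional cluster index whose field is omitted
#'   (used for the open-cluster local environment, whose self term comes
#'   from the quasi-static approximation instead).
#' @return named vector `c(c = , b = )` of free Ca2+ and free mobile
#'   buffer concentrations (µM).
#' @export
evaluate_field <- function(state, point, exclude_source = NULL) {
  p <- state$p
  r <- sqrt(sum(point^2))
  if (r >= p$cell_radius) {
    stop("evaluation point lies outside the cell", call. = FALSE)
  }
  mt <- state$modes
  n_cl <- dim(state$A)[1]
  cval <- p$c0 + state$u[1]
  bval <- p$b0 + state$u[2]
  pt_basis <- sph_bessel_by_mode(mt, r)
  for (s in seq_len(n_cl)) {
    if (!is.null(exclude_source) && s == exclude_source) next
    src <- state$layout$positions[s, ]
    if (state$currents[s] != 0) {
      sf <- static_pair_field(state$kern, src, point, p$cell_radius,
                              coefs = state$corr[[s]])
      cval <- cval + state$currents[s] * sf[["c"]]
      bval <- bval + state$currents[s] * sf[["b"]]
    }
    r_s <- sqrt(sum(src^2))
    cosg <- if (r_s < 1e-12 || r < 1e-12) 1 else
      max(-1, min(1, sum(src * point) / (r_s * r)))
    Pl <- legendre_values(mt$l_max, cosg)
    geo <- pt_basis * state$src_basis[s, ] * Pl[mt$l + 1] *
      (2 * mt$l + 1) / (4 * pi * mt$norm)
    cval <- cval + sum(geo * rowSums(mt$res_c * state$A[s, , ]))
    bval <- bval + sum(geo * rowSums(mt$res_b * state$A[s, , ]))
  }
  c(c = cval, b = bval)
}

#' Volume-averaged concentrations
#'
#' Only the uniform component contributes: the static split is
#' zero-average and every k > 0 no-flux mode integrates to zero over the
#' cell (orthogonality of the Legendre/Bessel basis).
#'
#' @param state a [field_state()].
#' @return named vector `c(c_avg = , b_avg = )` (µM).
#' @export
average_concentrations <- function(state) {
  c(c_avg = state$p$c0 + state$u[1], b_avg = state$p$b0 + state$u[2])
}

#' Average lumenal concentration
#'
#' @param state a [field_state()].
#' @return E_avg (µM).
#' @export
average_er <- function(state) state$p$E0 + state$u[4]

#' Advance the ER average alone
#'
#' Volume-ratio-weighted balance of pump influx, leak efflux and the total
#' channel efflux, with the cytosolic average held at its current value
#' over the step: `dE/dt = gamma (pump c_dev - leak E_dev - J/V)` in
#' deviations. Module-level ER balance; the engine advances the fully
#' coupled uniform system instead.
#'
#' @param state a [field_state()].
#' @param dt step (s), positive.
#' @param total_flux summed channel current (µM µm³/s).
#' @return The state with updated `E_avg` deviation.
#' @export
step_er <- function(state, dt, total_flux) {
  stopifnot(dt > 0)
  p <- state$p
  a <- -p$gamma * p$leak_rate
  drive <- p$gamma * (p$pump_rate * state$u[1] - total_flux / state$V_cell)
  state$u[4] <- state$u[4] * exp(a * dt) + drive * phi_exp(a, dt)
  state
}

#' Total cell calcium of a field state
#'
#' Free cytosolic average plus buffer-bound content plus the
#' volume-weighted ER content; conserved by the source-free dynamics and
#' under channel transport (channels only move Ca2+ between compartments).
#'
#' @param state a [field_state()].
#' @return total calcium per cytosolic volume (µM).
#' @export
total_calcium <- function(state) {
  p <- state$p
  # bound buffer deviations are the negatives of the free-buffer deviations
  (p$c0 + state$u[1]) + (p$B_m - p$b0 - state$u[2]) +
    (p$B_i - p$h0 - state$u[3]) + (p$E0 + state$u[4]) / p$gamma
}
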