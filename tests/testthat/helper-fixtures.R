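# shared fixtures: small parameter sets, layouts and oracles used across
# the suite. Everything is built in code at test time.

fast_params <- function(...) phys_params(...)

# two-cluster layout on the z axis, well inside the cell
two_cluster_layout <- function(d = 2, n_channels = c(8L, 8L)) {
  cluster_layout(rbind(c(0, 0, 1), c(0, 0, 1 + d)), n_channels)
}

# small mode table cached per test session
small_modes <- local({
  cache <- new.env()
  function(p = fast_params(), l_max = 10, n_max = 15) {
    key <- paste(l_max, n_max, signif(p$pump_rate, 8), signif(p$kon_i, 8),
                 signif(p$B_m, 8), sep = "_")
    if (is.null(cache[[key]])) cache[[key]] <- compute_modes(p, l_max, n_max)
    cache[[key]]
  }
})

# null-space stationary distribution of the subunit generator (oracle)
stationary_nullspace <- function(env, k = dyk_params()) {
  Q <- subunit_generator(env, k)
  e <- eigen(t(Q))
  v <- Re(e$vectors[, which.min(abs(e$values))])
  v <- v / sum(v)
  names(v) <- rownames(Q)
  v
}

# exact Gillespie simulation of one subunit chain at constant env (oracle);
# returns the sequence of visited states (encoded 0..7)
gillespie_subunit <- function(env, k, n_events, state0 = c(0L, 0L, 0L)) {
  s <- state0
  visits <- integer(n_events)
  for (i in seq_len(n_events)) {
    r <- subunit_transition_rates(s, env, k)
    pick <- sample.int(3, 1, prob = r / sum(r))
    s <- as.integer(strsplit(names(r)[pick], "")[[1]])
    visits[i] <- s[1] * 4L + s[2] * 2L + s[3]
  }
  visits
}

# radial finite-volume oracle for the stationary single-source problem
# (two diffusing species; the immobile buffer drops out at stationarity)
radial_fd_static <- function(p, I, n = 2000, r0 = 2e-3) {
  lr <- caspike:::linearized_rates(p)
  R <- p$cell_radius
  r_edge <- exp(seq(log(r0), log(R), length.out = n + 1))
  r_c <- sqrt(r_edge[-1] * r_edge[-(n + 1)])
  vol <- 4 / 3 * pi * diff(r_edge^3)
  area <- 4 * pi * r_edge^2
  iv <- integer(0); jv <- integer(0); xv <- numeric(0)
  add <- function(i, j, v) {
    iv[length(iv) + 1] <<- i; jv[length(jv) + 1] <<- j
    xv[length(xv) + 1] <<- v
  }
  lap <- function(D, off) for (i in 1:n) {
    if (i > 1) {
      w <- D * area[i] / (r_c[i] - r_c[i - 1])
      add(off + i, off + i, -w); add(off + i, off + i - 1, w)
    }
    if (i < n) {
      w <- D * area[i + 1] / (r_c[i + 1] - r_c[i])
      add(off + i, off + i, -w); add(off + i, off + i + 1, w)
    }
  }
  lap(p$D_c, 0); lap(p$D_b, n)
  alpha <- lr$theta_b + p$pump_rate
  for (i in 1:n) {
    add(i, i, -alpha * vol[i]); add(i, n + i, -lr$phi_b * vol[i])
    add(n + i, i, -lr$theta_b * vol[i]); add(n + i, n + i, -lr$phi_b * vol[i])
  }
  rhs <- numeric(2 * n); rhs[1] <- -I
  M <- Matrix::sparseMatrix(i = iv, j = jv, x = xv, dims = c(2 * n, 2 * n))
  u <- as.numeric(Matrix::solve(M, rhs))
  list(r = r_c, c = u[1:n], b = u[(n + 1):(2 * n)],
       c_avg = I / (p$pump_rate * 4 / 3 * pi * R^3))
}
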