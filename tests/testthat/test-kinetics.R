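# DeYoung-Keizer subunit/channel kinetics

test_that("every subunit state has exactly 3 outgoing edges covering the cube", {
  env <- local_env(0.05, 0.1)
  edges <- character(0)
  for (s in 0:7) {
    bits <- caspike:::subunit_bits(s)[1, ]
    r <- subunit_transition_rates(bits, env)
    expect_length(r, 3)
    expect_true(all(r >= 0))
    from <- paste0(bits, collapse = "")
    edges <- c(edges, paste(pmin(from, names(r)), pmax(from, names(r))))
  }
  # 24 directed = 12 undirected edges of the cube
  expect_length(unique(edges), 12)
})

test_that("zero ligand concentrations leave only unbinding transitions", {
  env <- local_env(0, 0)
  for (s in 0:7) {
    bits <- caspike:::subunit_bits(s)[1, ]
    r <- subunit_transition_rates(bits, env)
    binding <- (bits == 0)  # edges flipping a 0 bit are binding edges
    expect_true(all(r[binding] == 0))
    expect_true(all(r[!binding] > 0))
  }
})

test_that("rates from the fully unbound state follow the linear rate law", {
  k <- dyk_params()
  env <- local_env(0.05, 0.1)
  r <- subunit_transition_rates(c(0L, 0L, 0L), env, k)
  # hand substitution: IP3 binding a1*ip3, activation a5*c, inhibition a4*c
  expect_equal(unname(r["100"]), 400 * 0.1)
  expect_equal(unname(r["010"]), 20 * 0.05)
  expect_equal(unname(r["001"]), 0.2 * 0.05)
})

test_that("generator rows sum to zero and stationary distribution sums to 1", {
  env <- local_env(0.13, 0.21)
  Q <- subunit_generator(env)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  p <- caspike:::subunit_stationary(env)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
})

test_that("channel opens iff at least three subunits are active", {
  act <- c(1L, 1L, 0L)
  inh <- c(1L, 1L, 1L)
  rest <- c(0L, 0L, 0L)
  expect_true(channel_is_open(rbind(act, act, act, act)))
  expect_true(channel_is_open(rbind(act, act, act, inh)))
  expect_false(channel_is_open(rbind(act, act, inh, rest)))
})

test_that("stationary open probability matches the generator null-space oracle", {
  k <- dyk_params()
  for (cc in c(0.02, 0.1, 0.5, 2)) {
    env <- local_env(cc, 0.1)
    pa <- stationary_nullspace(env, k)[["110"]]
    oracle <- pa^4 + 4 * pa^3 * (1 - pa)
    expect_equal(stationary_open_probability(cc, 0.1, k), oracle,
                 tolerance = 1e-10)
  }
})

test_that("open probability is biphasic in Ca2+ and vanishes at zero Ca2+", {
  p_low <- stationary_open_probability(1e-4, 0.1)
  p_mid <- stationary_open_probability(0.1, 0.1)
  p_high <- stationary_open_probability(10, 0.1)
  expect_lt(p_low, 1e-6)
  expect_gt(p_mid, p_low)
  expect_gt(p_mid, p_high)
  expect_equal(stationary_open_probability(0, 0.1), 0)
})

test_that("raising IP3 at moderate Ca2+ does not decrease open probability", {
  ip3s <- c(0.05, 0.1, 0.2, 0.5)
  po <- vapply(ip3s, function(i) stationary_open_probability(0.1, i),
               numeric(1))
  expect_true(all(diff(po) >= 0))
})

test_that("hybrid sampling at constant env reduces to exponential waiting times", {
  k <- dyk_params()
  env_const <- function(t) local_env(0.05, 0.1)
  ch <- list(rep(0L, 4))  # one channel, all subunits unbound
  # total propensity of 4 unbound subunits
  lam <- 4 * sum(subunit_transition_rates(c(0L, 0L, 0L), env_const(0), k))
  set.seed(42)
  waits <- replicate(400, {
    ev <- hybrid_next_event(ch, env_const, 0, 1e3, k)
    ev$time
  })
  # exponential with rate lam: compare mean within 4 standard errors
  expect_lt(abs(mean(waits) - 1 / lam), 4 / lam / sqrt(length(waits)))
  expect_gt(stats::ks.test(waits, "pexp", lam)$p.value, 1e-4)
})

test_that("no transition is reported when total propensity vanishes", {
  env0 <- function(t) local_env(0, 0)
  ch <- list(rep(0L, 4))
  set.seed(1)
  expect_null(hybrid_next_event(ch, env0, 0, 100))
})

test_that("hybrid sampler integrates time-varying propensities", {
  # single subunit in (0,0,0) with only activation possible under a ramp
  # c(t) = beta t: first-binding time has survival exp(-a5 beta t^2/2).
  k <- dyk_params(a1 = 1e-12, a4 = 1e-12)  # suppress other bindings
  beta <- 0.2
  env_ramp <- function(t) local_env(beta * t, 0)
  set.seed(7)
  waits <- replicate(300, {
    ev <- hybrid_next_event(list(rep(0L, 1)), env_ramp, 0, 1e3, k)
    ev$time
  })
  rate <- k$a[5] * beta
  # survival S(t) = exp(-rate t^2 / 2) -> mean sqrt(pi/(2 rate))
  expect_equal(mean(waits), sqrt(pi / (2 * rate)),
               tolerance = 4 * sd(waits) / sqrt(length(waits)) /
                 sqrt(pi / (2 * rate)))
})
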