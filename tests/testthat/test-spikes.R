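# spike detection and ISI statistics

test_that("threshold crossing detection with debounce", {
  t <- seq(0, 300, by = 0.1)
  x <- rep(0.05, length(t))
  onsets <- c(30, 90, 150, 210, 270)
  for (o in onsets) x[t >= o & t < o + 5] <- 1.0
  tr <- detect_spikes(data.frame(time = t, c_avg = x))
  expect_length(tr, 5)
  expect_equal(as.numeric(tr), onsets, tolerance = 0.11)

  # flat trace: no spikes
  expect_length(detect_spikes(data.frame(time = t,
                                         c_avg = rep(0.05, length(t)))), 0)

  # debounce: two crossings 1 s apart count once with min_separation 5 s
  y <- rep(0.05, length(t))
  y[t >= 10 & t < 10.3] <- 1; y[t >= 11 & t < 11.3] <- 1
  expect_length(detect_spikes(data.frame(time = t, c_avg = y),
                              min_separation = 5), 1)
  expect_length(detect_spikes(data.frame(time = t, c_avg = y),
                              min_separation = 0.5), 2)

  expect_error(detect_spikes(data.frame(time = t, c_avg = y),
                             threshold = 0.01), "resting")
})

test_that("detection is invariant to resampling finer than min_separation/4", {
  mk <- function(dt) {
    t <- seq(0, 300, by = dt)
    x <- rep(0.05, length(t))
    for (o in c(40, 100, 170)) x[t >= o & t < o + 4] <- 0.9
    as.numeric(detect_spikes(data.frame(time = t, c_avg = x)))
  }
  expect_equal(length(mk(0.5)), length(mk(0.05)))
  expect_equal(mk(0.5), mk(0.05), tolerance = 0.6)
})

test_that("ISI statistics: arithmetic and shifted-exponential limits", {
  expect_error(isi_stats(spike_train(c(0, 10))), "at least 3")
  s <- isi_stats(spike_train(c(0, 10, 30, 60)))
  expect_equal(s$T_av, 20)
  expect_equal(s$sigma, 10)
  expect_equal(s$n_isi, 3)

  per <- isi_stats(spike_train(seq(0, 300, by = 30)))
  expect_equal(per$T_av, 30)
  expect_equal(per$sigma, 0)

  tr <- surrogate_trains(1e4, delta = 20, mean_exp = 30, seed = 2)[[1]]
  s2 <- isi_stats(tr)
  expect_lt(abs(s2$sigma - 30) / 30, 0.05)
  expect_lt(abs(s2$T_av - 50) / 50, 0.05)
})

test_that("regression recovers exact lines to machine precision", {
  T_av <- c(30, 45, 60, 80)
  pts <- data.frame(T_av = T_av, sigma = T_av - 20)
  r <- sigma_tav_regression(pts, n_boot = 0)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$T_offset, 20, tolerance = 1e-10)

  pts2 <- data.frame(T_av = T_av, sigma = 0.6 * T_av - 12)
  r2 <- sigma_tav_regression(pts2, n_boot = 0)
  expect_equal(r2$slope, 0.6, tolerance = 1e-12)

  expect_error(sigma_tav_regression(
    data.frame(T_av = c(30, 30, 30), sigma = c(1, 2, 3))), "degenerate")
  expect_error(sigma_tav_regression(pts[1:2, ]), "at least 3")
})

test_that("surrogate populations give slope 1 and the refractory offset", {
  set.seed(9)
  trains <- surrogate_trains(200, delta = 20,
                             mean_exp = seq(10, 80, length.out = 30),
                             seed = 31)
  pts <- lapply(trains, isi_stats)
  r <- sigma_tav_regression(pts, n_boot = 200, seed = 5)
  expect_lt(abs(r$slope - 1), 0.1)
  expect_lt(abs(r$T_offset - 20), 3)
  expect_true(is.finite(r$slope_se) && r$slope_se > 0)
})

test_that("population slopes are computed per condition and match their
           generating lines", {
  g1 <- data.frame(T_av = c(30, 50, 70), sigma = c(10, 30, 50))
  g2 <- data.frame(T_av = c(30, 50, 70), sigma = 0.6 * c(30, 50, 70) - 12)
  res <- population_slope(list(a = g1, b = g2), n_boot = 0)
  expect_equal(res$a$slope, 1, tolerance = 1e-12)
  expect_equal(res$b$slope, 0.6, tolerance = 1e-12)
  # identical clouds give identical slopes
  res2 <- population_slope(list(x = g1, y = g1), n_boot = 0)
  expect_identical(res2$x$slope, res2$y$slope)
  expect_error(population_slope(list(a = g1[1:2, ])), "at least 3")
})

test_that("regularity sweeps: gamma-ISI surrogates reduce sigma below the
           exponential line", {
  exp_tr <- surrogate_trains(2000, delta = 0, mean_exp = 40, shape = 1,
                             seed = 3)[[1]]
  reg_tr <- surrogate_trains(2000, delta = 0, mean_exp = 40, shape = 8,
                             seed = 3)[[1]]
  expect_lt(isi_stats(reg_tr)$sigma, isi_stats(exp_tr)$sigma / 2)
})
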