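# whole-cell event loop

test_that("a cell without channels stays exactly at rest", {
  layout <- cluster_layout(rbind(c(0, 0, 2), c(0, 0, -2)), c(0L, 0L))
  cfg <- sim_config(layout = layout, t_end = 5, seed = 1,
                    l_max = 4, n_max = 6)
  ts <- run_cell(cfg)
  expect_true(all(ts$c_avg == cfg$p$c0))
  expect_true(all(ts$E_avg == cfg$p$E0))
  expect_true(all(ts$n_open == 0))
  expect_equal(nrow(attr(ts, "events")), 0)
})

test_that("identical configurations give bit-identical output", {
  cfg <- sim_config(n_clusters = 3, channel_range = c(6L, 10L),
                    t_end = 20, seed = 42, l_max = 6, n_max = 8)
  t1 <- run_cell(cfg)
  t2 <- run_cell(cfg)
  expect_identical(t1$c_avg, t2$c_avg)
  expect_identical(attr(t1, "events"), attr(t2, "events"))
  expect_identical(attr(t1, "final")$A, attr(t2, "final")$A)
  # a different seed gives a different trajectory
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(run_cell(cfg2)$c_avg, t1$c_avg))
})

test_that("channel bookkeeping is consistent at the final state", {
  cfg <- sim_config(n_clusters = 4, channel_range = c(4L, 8L),
                    t_end = 30, seed = 5, l_max = 6, n_max = 8,
                    record_cluster_open = TRUE)
  ts <- run_cell(cfg)
  fin <- attr(ts, "final")
  layout <- attr(ts, "layout")
  # recompute open channels from subunit states
  sub <- fin$sub_state
  ch_of_sub <- rep(seq_len(sum(layout$channels)), each = 4)
  active <- tapply(sub == 6L, ch_of_sub, sum)
  cl_of_ch <- rep(seq_along(layout$channels), layout$channels)
  n_open <- tapply(active >= 3, cl_of_ch, sum)
  expect_equal(unname(as.integer(n_open)), fin$n_open)
  # event log: per-cluster open counts change by +-1 and currents are zero
  # exactly when the cluster is closed
  ev <- attr(ts, "events")
  if (nrow(ev)) {
    expect_true(all((ev$current == 0) == (ev$n_open == 0)))
    for (k in unique(ev$cluster)) {
      e <- ev[ev$cluster == k, ]
      expect_true(all(abs(diff(c(0, e$n_open))) == 1))
    }
    # per-cluster open counts at record times sum to the total
    expect_equal(rowSums(attr(ts, "cluster_open")), ts$n_open)
  }
})

test_that("a single cluster produces isolated puffs, not sustained opening", {
  cfg <- sim_config(n_clusters = 1, channel_range = c(10L, 10L),
                    t_end = 60, seed = 7, l_max = 6, n_max = 10)
  ts <- run_cell(cfg)
  ev <- attr(ts, "events")
  expect_gt(nrow(ev), 0)                # release events occur
  expect_lt(mean(ts$n_open > 0), 0.5)   # but mostly quiescent
  expect_true(all(ts$c_avg < 1))        # no runaway
  # ER is depleted by release, never enriched above equilibrium
  expect_true(all(ts$E_avg <= cfg$p$E0 + 1e-9))
})

test_that("engine local environments match an R-side field replay", {
  layout <- cluster_layout(rbind(c(0, 0, 1), c(0, 0, 3), c(1.5, 0, 1)),
                           c(10L, 10L, 10L))
  p <- phys_params()
  cfg <- sim_config(p = p, layout = layout, t_end = 15, seed = 5,
                    l_max = 10, n_max = 14)
  ts <- run_cell(cfg)
  fin <- attr(ts, "final")
  mt <- compute_modes(p, cfg$l_max, cfg$n_max)
  st <- field_state(layout, mt, p)
  h <- history_of_run(ts)
  st <- advance_field_history(st, h, cfg$t_end)
  expect_equal(st$u, fin$u, tolerance = 1e-10)
  envs <- vapply(1:3, function(k) local_env_at_cluster(k, st, h, p)$c,
                 numeric(1))
  expect_equal(envs, fin$c_loc, tolerance = 1e-3)
})

test_that("strict per-event refresh and 1 ms coalescing agree statistically", {
  mk <- function(refresh) {
    cfg <- sim_config(n_clusters = 1, channel_range = c(8L, 8L),
                      t_end = 40, seed = 9, l_max = 4, n_max = 6,
                      env_refresh = refresh)
    ts <- run_cell(cfg)
    mean(ts$n_open)
  }
  f_strict <- mk(0)
  f_coal <- mk(1e-3)
  # same open-fraction scale (loose: stochastic trajectories differ)
  expect_lt(abs(f_strict - f_coal), 0.15)
})

test_that("grid snapshots agree with point evaluation and show the local
           concentration scale of an open cluster", {
  p <- phys_params()
  layout <- cluster_layout(matrix(c(0, 0, 2), 1, 3), 8L)
  mt <- compute_modes(p, 8, 12)
  st <- field_state(layout, mt, p)
  g0 <- snapshot_grid(st, resolution = 8)
  inside <- !is.na(g0$c)
  expect_true(all(abs(g0$c[inside] - p$c0) < 1e-12))

  I <- cluster_current(8, p$c0, p$E0, p)
  st <- advance_field(st, 1.0, I)
  g <- snapshot_grid(st, resolution = 8)
  ix <- c(5, 4, 6)  # an interior node
  pt <- c(g$axis[5], g$axis[4], g$axis[6])
  expect_equal(g$c[5, 4, 6], evaluate_field(st, pt)[["c"]],
               tolerance = 1e-12)
  # the 2 uM iso-surface around the source is non-empty: points 0.2 um
  # from an open 8-channel cluster exceed 2 uM
  near <- evaluate_field(st, c(0, 0, 2.2))[["c"]]
  expect_gt(near, 2)
})

test_that("manifest from a run rebuilds a configuration that reproduces it", {
  cfg <- sim_config(n_clusters = 2, channel_range = c(6L, 6L),
                    t_end = 10, seed = 21, l_max = 5, n_max = 6)
  ts <- run_cell(cfg)
  man <- attr(ts, "manifest")
  cfg2 <- config_from_manifest(man)
  ts2 <- run_cell(cfg2)
  expect_identical(ts$c_avg, ts2$c_avg)
  expect_identical(attr(ts, "events"), attr(ts2, "events"))
})
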