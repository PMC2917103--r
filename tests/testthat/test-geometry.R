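# cell geometry and cluster layouts

test_that("generated layouts satisfy all invariants and are reproducible", {
  layout <- generate_layout(47, c(4L, 16L), min_sep = 1, max_nn = 7,
                            seed = 11)
  expect_equal(nrow(layout$positions), 47)
  expect_length(layout$channels, 47)
  expect_true(all(layout$channels >= 4 & layout$channels <= 16))
  r <- sqrt(rowSums(layout$positions^2))
  expect_true(all(r < layout$cell$radius))
  d <- as.matrix(stats::dist(layout$positions)); diag(d) <- Inf
  expect_gte(min(d), 1)
  nn <- nearest_neighbor_distances(layout)
  expect_true(all(nn >= 1 & nn <= 7))
  # bit-reproducibility under the same seed
  layout2 <- generate_layout(47, c(4L, 16L), min_sep = 1, max_nn = 7,
                             seed = 11)
  expect_identical(layout, layout2)
  expect_false(identical(
    layout$positions,
    generate_layout(47, c(4L, 16L), seed = 12)$positions))
})

test_that("degenerate layouts behave per contract", {
  one <- generate_layout(1, c(10L, 10L), seed = 1)
  expect_equal(nrow(one$positions), 1)
  expect_identical(nearest_neighbor_distances(one), numeric(0))

  two <- generate_layout(2, c(4L, 8L), min_sep = 1, seed = 2)
  expect_gte(nearest_neighbor_distances(two)[1], 1)
})

test_that("nearest-neighbour distances match the pairwise matrix", {
  layout <- cluster_layout(rbind(c(0, 0, 0), c(3, 0, 0)), c(4L, 4L))
  expect_equal(nearest_neighbor_distances(layout), c(3, 3))
  layout3 <- generate_layout(12, c(4L, 8L), seed = 5)
  d <- as.matrix(stats::dist(layout3$positions)); diag(d) <- Inf
  expect_equal(nearest_neighbor_distances(layout3), unname(apply(d, 1, min)))
})

test_that("infeasible packings raise an explicit error", {
  expect_error(generate_layout(1000, c(4L, 8L), min_sep = 2,
                               cell = cell_shape(5), seed = 1),
               "packing|failed to place")
  expect_error(generate_layout(40, c(4L, 8L), min_sep = 3.5, max_nn = 3.6,
                               cell = cell_shape(10), seed = 1,
                               max_attempts = 5),
               "failed to place")
})

test_that("positions are uniform in the ball (radial chi-squared)", {
  # pool many small layouts without separation constraints
  rad <- unlist(lapply(1:40, function(s) {
    l <- generate_layout(25, c(4L, 8L), min_sep = 1e-6, max_nn = Inf,
                         seed = 1000 + s)
    sqrt(rowSums(l$positions^2))
  }))
  # uniform in volume: CDF (r/R)^3; coarse bins
  breaks <- c(0, (1:4 / 4)^(1 / 3) * 10)
  obs <- table(cut(rad, breaks))
  pv <- stats::chisq.test(obs, p = rep(0.25, 4))$p.value
  expect_gt(pv, 1e-3)
})

test_that("layouts round-trip through the tabular text format", {
  layout <- generate_layout(6, c(4L, 8L), seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_layout(layout, path)
  back <- read_layout(path)
  expect_equal(back$positions, layout$positions, tolerance = 1e-12)
  expect_equal(back$channels, layout$channels)
})
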