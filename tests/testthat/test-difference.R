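test_that("CVA magnitude is the per-pixel spectral change norm", {
  pre <- scene_from_bands(matrix(10, 2, 2), matrix(20, 2, 2), matrix(30, 2, 2))
  post <- scene_from_bands(matrix(10, 2, 2), matrix(24, 2, 2), matrix(33, 2, 2))
  expect_equal(cva_magnitude(pre, post), matrix(5, 2, 2))    # sqrt(0+16+9)
  expect_equal(cva_magnitude(pre, pre), matrix(0, 2, 2))

  # single band reduces to an absolute difference
  r1 <- band_roles("custom", red = 1, nir = 2, mir = 3, cva_bands = 2)
  g <- matrix(rnorm(16), 4, 4)
  a <- scene_from_bands(g * 0, g, g * 0, roles = r1)
  b <- scene_from_bands(g * 0, g * 0, g * 0, roles = r1)
  expect_equal(cva_magnitude(a, b), abs(g))
  expect_true(all(cva_magnitude(a, b) >= 0))
  expect_error(cva_magnitude(a, scene_from_bands(matrix(0, 3, 3),
                                                 matrix(0, 3, 3),
                                                 matrix(0, 3, 3))),
               "shape")
})

test_that("NDVI and NBR are guarded normalized ratios", {
  s <- scene_from_bands(matrix(0.2, 1, 1), matrix(0.6, 1, 1), matrix(0.1, 1, 1))
  expect_equal(ndvi(s)[1, 1], 0.5)              # (0.6-0.2)/0.8
  s2 <- scene_from_bands(matrix(0.1, 1, 1), matrix(0.5, 1, 1), matrix(0.1, 1, 1))
  expect_equal(nbr(s2)[1, 1], 0.4 / 0.6)
  # symmetry, bounds, zero-denominator guard
  eqs <- scene_from_bands(matrix(0.3, 1, 1), matrix(0.3, 1, 1), matrix(0.3, 1, 1))
  expect_equal(ndvi(eqs)[1, 1], 0)
  expect_equal(nbr(eqs)[1, 1], 0)
  ext <- scene_from_bands(matrix(0, 1, 1), matrix(1, 1, 1), matrix(0, 1, 1))
  expect_equal(ndvi(ext)[1, 1], 1)
  z <- scene_from_bands(matrix(0, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1))
  expect_equal(ndvi(z)[1, 1], 0)                # NIR + red == 0
  expect_equal(nbr(z)[1, 1], -1)
  set.seed(1)
  rs <- scene_from_bands(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8),
                         matrix(runif(64), 8, 8))
  expect_true(all(abs(ndvi(rs)) <= 1) && all(abs(nbr(rs)) <= 1))
})

test_that("index differences are pre minus post so burn change is positive", {
  expect_equal(index_difference(matrix(0.8, 1, 1), matrix(0.1, 1, 1))[1, 1], 0.7)
  g <- matrix(rnorm(9), 3, 3)
  expect_equal(index_difference(g, g), matrix(0, 3, 3))
  expect_equal(index_difference(g, g + 1), matrix(-1, 3, 3))   # index rose
  expect_error(index_difference(g, matrix(0, 2, 2)), "shape")
})

test_that("min-max normalization maps to [0,1] with a degenerate-constant guard", {
  expect_equal(minmax_normalize(matrix(c(0, 5, 10), 1)), matrix(c(0, 0.5, 1), 1))
  expect_equal(minmax_normalize(matrix(7, 3, 3)), matrix(0, 3, 3))
  set.seed(2)
  g <- matrix(rnorm(100), 10, 10)
  n <- minmax_normalize(g)
  expect_equal(range(n), c(0, 1))
})

test_that("fusion weights are normalized component SDs and the fused image stays in [0,1]", {
  base <- matrix(rep(c(0, 0.2), each = 2), 2, 2)    # sd ratio 1:2:1 by scaling
  dp <- fuse_differences(base, 2 * base, base)
  expect_equal(unname(dp$weights), c(0.25, 0.5, 0.25))
  expect_equal(sum(dp$weights), 1, tolerance = 1e-9)
  expect_equal(dp$di,
               minmax_normalize(0.25 * base + 0.5 * (2 * base) + 0.25 * base),
               tolerance = 1e-9)

  # identical normalized components pass through unchanged
  set.seed(3)
  v <- minmax_normalize(matrix(runif(64), 8, 8))
  expect_equal(fuse_differences(v, v, v)$di, v, tolerance = 1e-9)

  # a constant component carries zero weight; all-constant is an error
  dp2 <- fuse_differences(v, matrix(0.5, 8, 8), v)
  expect_equal(unname(dp2$weights[2]), 0)
  expect_error(fuse_differences(matrix(1, 2, 2), matrix(0, 2, 2),
                                matrix(0.5, 2, 2)),
               "no change signal")
})

test_that("separability reports the normalized class distance and histogram overlap", {
  # oracle: direct evaluation of D from the raw class values
  set.seed(4)
  truth <- matrix(rep(c(1, 0), each = 32), 8, 8)
  di <- matrix(0, 8, 8)
  di[truth == 1] <- runif(32, 0.7, 0.9)
  di[truth == 0] <- runif(32, 0.1, 0.3)
  rep <- separability(di, truth)
  d_direct <- abs(mean(di[truth == 1]) - mean(di[truth == 0])) /
    (sd(di[truth == 1]) + sd(di[truth == 0]))
  expect_equal(rep$d_value, d_direct, tolerance = 1e-9)
  expect_equal(rep$overlap_fraction, 0)          # disjoint supports

  # identical class distributions: D ~ 0, overlap ~ 1
  di2 <- matrix(rep(seq(0, 1, length.out = 32), 2), 8, 8)
  rep2 <- separability(di2, truth)
  expect_lt(rep2$d_value, 0.05)
  expect_gt(rep2$overlap_fraction, 0.95)

  expect_error(separability(di, matrix(1, 8, 8)), "empty")

  # serialization of the report
  d <- withr::local_tempdir()
  write_separability(rep, json_path = file.path(d, "sep.json"),
                     csv_path = file.path(d, "sep.csv"))
  j <- jsonlite::read_json(file.path(d, "sep.json"))
  expect_equal(j$d_value, rep$d_value, tolerance = 1e-9)
  h <- read.csv(file.path(d, "sep.csv"))
  expect_equal(nrow(h), 64)
  expect_equal(sum(h$burn_count), 32)
})
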