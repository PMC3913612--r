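test_that("the NIR regression recovers exact and noisy linear relations", {
  x1 <- matrix(c(1, 2, 3, 4), 2, 2)
  f <- fit_nir(x1, 2 * x1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$residual_variance, 0, tolerance = 1e-12)
  f2 <- fit_nir(x1, x1)
  expect_equal(c(f2$slope, f2$intercept), c(1, 0), tolerance = 1e-12)
  expect_error(fit_nir(matrix(1, 2, 2), x1), "constant")

  set.seed(5)
  x <- matrix(runif(1e4), 100, 100)
  y <- 3 * x + 1 + matrix(rnorm(1e4, sd = 0.01), 100, 100)
  f3 <- fit_nir(x, y)
  expect_lt(abs(f3$slope - 3), 0.01)
  expect_lt(abs(f3$intercept - 1), 0.01)
})

test_that("fitting errors are variance-scaled squared residuals", {
  fit <- structure(list(slope = 1, intercept = 0, residual_variance = 0.25),
                   class = "regression_fit")
  x1 <- matrix(c(1, 1, 1), 1, 3)
  x2 <- matrix(c(1, 1.5, 2), 1, 3)              # residuals 0, d, 2d with d=0.5
  expect_equal(fitting_error(x1, x2, fit), matrix(c(0, 1, 4), 1, 3))

  # mean error is exactly 1 when the fit comes from the same data
  set.seed(6)
  a <- matrix(runif(400), 20, 20)
  b <- 2 * a + matrix(rnorm(400, sd = 0.1), 20, 20)
  f <- fit_nir(a, b)
  expect_equal(mean(fitting_error(a, b, f)), 1, tolerance = 1e-9)

  # Mahalanobis normalization cancels a joint rescaling
  s <- 37.5
  fs <- fit_nir(s * a, s * b)
  expect_equal(fitting_error(s * a, s * b, fs), fitting_error(a, b, f),
               tolerance = 1e-6)

  fit0 <- structure(list(slope = 1, intercept = 0, residual_variance = 0),
                    class = "regression_fit")
  expect_error(fitting_error(a, b, fit0), "no-change")
})

test_that("the 1-D two-cluster split matches the exhaustive partition oracle", {
  sp <- kmeans_split(c(0, 0, 0, 10, 10))
  expect_equal(sp$centers, c(0, 10))
  expect_equal(sp$labels, c(1L, 1L, 1L, 2L, 2L))

  set.seed(7)
  for (i in 1:20) {
    v <- round(runif(sample(4:12, 1), 0, 10), 2)
    if (length(unique(v)) < 2) next
    sp <- kmeans_split(v)
    oracle <- exhaustive_two_partition(v)
    expect_equal(within_sse(v, sp$labels), oracle$sse, tolerance = 1e-9)
  }

  # separated clusters are recovered and the seed plays no role
  set.seed(8)
  v <- c(rnorm(50, 0, 1), rnorm(50, 10, 1))
  lab <- kmeans_split(v, seed = 1)$labels
  expect_equal(lab, rep(1:2, each = 50))
  expect_equal(kmeans_split(v, seed = 99)$labels, lab)
  expect_error(kmeans_split(rep(3, 5)), "distinct")
})

test_that("the automatic contour localizes an induced NIR change", {
  set.seed(9)
  h <- 40; w <- 40
  pre_nir <- matrix(100 + rnorm(h * w, sd = 2), h, w)
  post_nir <- pre_nir + matrix(rnorm(h * w, sd = 1), h, w)
  patch <- matrix(FALSE, h, w); patch[10:25, 12:28] <- TRUE
  post_nir[patch] <- 0.5 * pre_nir[patch]        # NIR halved inside the patch
  init <- auto_initial_contour(nir_scene(pre_nir), nir_scene(post_nir))
  expect_equal(init$source, "auto")
  expect_true(all(init$mask[patch] == 1))         # mask covers the patch
  expect_lte(sum(init$mask), 1.2 * sum(patch))    # without gross overshoot
  expect_equal(sum(init$mask), sum(init$phi0 > 0))
  expect_true(all(init$phi0 %in% c(-2, 2)))
})

test_that("a no-change scene is reported rather than segmented", {
  pre <- matrix(rep(1:4, 4), 4, 4)
  expect_error(auto_initial_contour(nir_scene(pre), nir_scene(pre)),
               "no-change")
})

test_that("rectangle tiling covers the image periodically", {
  init <- rectangle_initial_contour(c(32, 32), 8)
  expect_equal(init$source, "rectangles")
  expect_equal(max(EBImage::bwlabel(init$mask)), 16)
  expect_gt(sum(init$mask), 0)
  expect_lt(sum(init$mask), 32 * 32)
  m <- init$mask
  expect_identical(m[1:24, ], m[9:32, ])          # translation period 8
  expect_identical(m[, 1:24], m[, 9:32])
  expect_error(rectangle_initial_contour(c(32, 32), 3), "spacing")
  expect_error(rectangle_initial_contour(c(16, 16), 16), "spacing")
})
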