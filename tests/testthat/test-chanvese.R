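test_that("regularized Heaviside and Dirac have the closed-form properties", {
  expect_equal(heaviside_eps(0, 1), 0.5)
  expect_lt(abs(heaviside_eps(1e6, 1) - 1), 1e-6)
  z <- seq(-5, 5, by = 0.25)
  expect_equal(heaviside_eps(z, 2) + heaviside_eps(-z, 2), rep(1, length(z)))
  expect_true(all(diff(heaviside_eps(z, 0.5)) > 0))

  expect_equal(dirac_eps(0, 1), 1 / pi)
  expect_true(all(dirac_eps(z, 1) > 0))
  expect_equal(dirac_eps(z, 1), dirac_eps(-z, 1))
  # unit mass by numerical quadrature
  q <- stats::integrate(dirac_eps, -1e3, 1e3, epsilon = 1)$value
  expect_lt(abs(q - 1), 1e-3)
  # Dirac is the derivative of the Heaviside
  hstep <- 1e-5
  for (z0 in -2:2) {
    num <- (heaviside_eps(z0 + hstep, 1) - heaviside_eps(z0 - hstep, 1)) /
      (2 * hstep)
    expect_lt(abs(num - dirac_eps(z0, 1)), 1e-6)
  }
})

test_that("region means average the image inside and outside the contour", {
  phi <- matrix(rep(c(2, -2), each = 8), 4, 4)
  expect_equal(region_means(matrix(7, 4, 4), phi, 1), c(7, 7))

  u0 <- matrix(rep(c(0.9, 0.1), each = 8), 4, 4)
  cc <- region_means(u0, phi * 1000, epsilon = 1e-3)   # sharp step limit
  expect_equal(cc, c(0.9, 0.1), tolerance = 1e-4)
  expect_equal(region_means(u0, -phi, 1), rev(region_means(u0, phi, 1)))
  expect_error(region_means(matrix(NA_real_, 2, 2), matrix(1, 2, 2), 1),
               "zero weight")
})

test_that("curvature is zero on planes, 1/r on cones, and odd in phi", {
  plane <- outer(1:32, 1:32, function(i, j) 0.3 * i - 0.7 * j + 2)
  expect_lt(max(abs(curvature(plane)[3:30, 3:30])), 1e-8)

  ctr <- 32.5
  cone <- outer(1:64, 1:64, function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2))
  k <- curvature(cone)
  r <- cone
  sel <- r >= 5 & r <= 25                       # interior annulus
  expect_lt(max(abs(k[sel] * r[sel] - 1)), 0.1)

  set.seed(10)
  phi <- gauss_smooth(matrix(rnorm(900), 30, 30), 2)
  expect_equal(curvature(-phi), -curvature(phi), tolerance = 1e-9)
})

test_that("a single evolution step follows the update equation", {
  set.seed(11)
  phi <- gauss_smooth(matrix(rnorm(400), 20, 20), 1.5)
  p <- cv_params(dt = 0.5, mu = 0.2)
  # constant image, nu = 0: data terms cancel, only curvature smoothing acts
  u0 <- matrix(0.4, 20, 20)
  st <- evolve_step(u0, burnscar:::new_levelset_state(phi), p)
  expect_equal(st$phi - phi,
               p$dt * dirac_eps(phi, p$epsilon) * p$mu * curvature(phi),
               tolerance = 1e-12)
  expect_equal(st$iteration, 1L)

  # dt = 0 leaves phi unchanged
  p0 <- cv_params(dt = 0)
  st0 <- evolve_step(matrix(runif(400), 20, 20),
                     burnscar:::new_levelset_state(phi), p0)
  expect_equal(st0$phi, phi)
})

test_that("the energy vanishes on constants, is minimized by the region means, and is symmetric", {
  p <- cv_params()
  phi_far <- matrix(10, 6, 6)       # contour far from every pixel
  expect_lt(cv_energy(matrix(0.3, 6, 6), phi_far, p), 1e-6)

  set.seed(12)
  u0 <- matrix(runif(64), 8, 8)
  phi <- matrix(rnorm(64), 8, 8)
  cc <- region_means(u0, phi, p$epsilon)
  h <- heaviside_eps(phi, p$epsilon)
  data_energy <- function(c1, c2)
    sum((u0 - c1)^2 * h) + sum((u0 - c2)^2 * (1 - h))
  for (i in 1:10) {
    alt <- cc + rnorm(2, sd = 0.1)
    expect_gte(data_energy(alt[1], alt[2]), data_energy(cc[1], cc[2]))
  }

  # relabeling symmetry: (phi -> -phi, lambda1 <-> lambda2), nu = 0
  pa <- cv_params(lambda1 = 2, lambda2 = 0.7, nu = 0)
  pb <- cv_params(lambda1 = 0.7, lambda2 = 2, nu = 0)
  expect_equal(cv_energy(u0, phi, pa), cv_energy(u0, -phi, pb),
               tolerance = 1e-9)
})

test_that("the compiled evolution loop reproduces the reference steps", {
  set.seed(13)
  u0 <- matrix(runif(400), 20, 20)
  phi0 <- rectangle_initial_contour(c(20, 20), 5)$phi0
  p <- cv_params(max_iter = 10, tol = 0)
  st <- burnscar:::new_levelset_state(phi0)
  for (i in 1:10) st <- evolve_step(u0, st, p)
  res <- cv_segment(u0, phi0, p)
  expect_equal(res$phi, st$phi, tolerance = 1e-9)
  expect_equal(res$energy_trace, st$energy_trace, tolerance = 1e-9)
  expect_equal(.cpp_curvature(st$phi, 1e-8), curvature(st$phi),
               tolerance = 1e-12)
})

test_that("segmentation is a fixed point at an already-optimal contour", {
  dsk <- make_disk_image(c(48, 48), 0.8, 0.2, noise_sd = 0, seed = 0)
  phi0 <- ifelse(dsk$truth == 1, 2, -2)
  res <- cv_segment(dsk$image, phi0)
  expect_true(res$converged)
  expect_lt(res$iterations, cv_params()$max_iter / 10)
  expect_equal(unname(res$mask), unname(dsk$truth))
  expect_lt(tail(res$energy_trace, 1), res$energy_trace[1] + 1e-9)
  # binary-step magnitude does not matter
  res2 <- cv_segment(dsk$image, 2 * phi0)
  expect_equal(res2$mask, res$mask)
})

test_that("the mask ignores a constant intensity shift when nu = 0", {
  dsk <- make_disk_image(c(48, 48), 0.8, 0.2, noise_sd = 0.02, seed = 3)
  phi0 <- rectangle_initial_contour(c(48, 48), 12)$phi0
  p <- cv_params(nu = 0)
  r1 <- cv_segment(dsk$image, phi0, p)
  r2 <- cv_segment(dsk$image + 5, phi0, p)
  expect_equal(r1$mask, r2$mask)
  expect_false(isTRUE(all.equal(r1$c1, r1$c2)))
})

test_that("evolution diagnoses a destabilizing time step", {
  dsk <- make_disk_image(c(24, 24), 0.8, 0.2, noise_sd = 0, seed = 0)
  phi0 <- ifelse(dsk$truth == 1, 2, -2)
  expect_error(cv_segment(dsk$image, phi0, cv_params(dt = 1e200, mu = 1e200,
                                                     max_iter = 50, tol = 0)),
               "dt too large")
  expect_error(cv_segment(dsk$image, matrix(2, 24, 24)), "both signs")
})
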