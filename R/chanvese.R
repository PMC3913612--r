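#' Chan-Vese solver parameters
#'
#' Tuning constants of the region-based level-set model. Defaults suit a
#' difference image normalized to \[0, 1\]:
#'
#' * `mu` — contour-length penalty (weight of the curvature term).
#' * `nu` — inside-area penalty (0 disables it).
#' * `lambda1`, `lambda2` — data-term weights for the inside and outside
#'   regions.
#' * `epsilon` — width of the regularized Heaviside/Dirac (in phi units).
#' * `dt` — artificial-time step of the explicit gradient-descent update.
#' * `max_iter` — iteration cap.
#' * `tol`, `stop_window` — stop when the fraction of pixels whose sign
#'   of phi changed over the last `stop_window` iterations falls below
#'   `tol`.
#' * `min_iter` — warm-up floor before the stopping rule is consulted.
#'   With a binary-step phi0 the Dirac regularization makes the surface
#'   creep for some tens of iterations before the first pixel can change
#'   sign, so an unguarded sign-change test would declare convergence
#'   while the contour is still accelerating.
#' * `min_contrast` — minimal separation of the region means for the
#'   contour to count as converged, expressed as a fraction of the
#'   between-class mean separation of an Otsu split of the image. An
#'   initialization that samples both classes evenly (the tiled
#'   rectangles) starts in a metastable state with `c1 ~ c2` in which the
#'   mask barely moves for long stretches before symmetry breaks; during
#'   those phases the contour is static but not converged, and only the
#'   region-mean contrast tells the two situations apart. At an actual
#'   optimum the region means bracket the histogram's two classes, so
#'   half the Otsu separation is a floor any converged state clears.
#' * `patience` — number of consecutive iterations on which the full
#'   stopping test must hold. Symmetry breaking proceeds through bursts
#'   separated by lulls in which the contour is transiently still; the
#'   patience requirement rides out those lulls.
#'
#' @param mu,nu,lambda1,lambda2,epsilon,dt,max_iter,tol,stop_window,min_iter,min_contrast,patience
#'   see above.
#' @return An object of class `cv_params`.
#' @export
cv_params <- function(mu = 0.01, nu = 0, lambda1 = 1, lambda2 = 1,
                      epsilon = 1, dt = 0.5, max_iter = 6000L,
                      tol = 1e-4, stop_window = 10L, min_iter = 100L,
                      min_contrast = 0.5, patience = 50L) {
  stopifnot(mu >= 0, lambda1 > 0, lambda2 > 0, epsilon > 0, dt >= 0,
            max_iter >= 1, tol >= 0, stop_window >= 1, min_iter >= 0,
            min_contrast >= 0, patience >= 1)
  structure(list(mu = mu, nu = nu, lambda1 = lambda1, lambda2 = lambda2,
                 epsilon = epsilon, dt = dt, max_iter = as.integer(max_iter),
                 tol = tol, stop_window = as.integer(stop_window),
                 min_iter = as.integer(min_iter),
                 min_contrast = min_contrast,
                 patience = as.integer(patience)),
            class = "cv_params")
}

#' Regularized Heaviside function
#'
#' `H_eps(z) = 0.5 * (1 + (2/pi) * atan(z/eps))`: a smooth, strictly
#' increasing step with limits 0 and 1 and `H(0) = 0.5`.
#'
#' @param z numeric (vectorized).
#' @param epsilon regularization width, > 0.
#' @return Values in (0, 1).
#' @export
heaviside_eps <- function(z, epsilon = 1) {
  stopifnot(epsilon > 0)
  0.5 * (1 + (2 / pi) * atan(z / epsilon))
}

#' Regularized Dirac delta
#'
#' `delta_eps(z) = (1/pi) * eps / (eps^2 + z^2)`, the derivative of
#' [heaviside_eps()]: even, positive, unit mass. It localizes the
#' level-set update around the zero level while keeping every pixel
#' weakly active, which is what lets the contour develop new components
#' far from its current position.
#'
#' @inheritParams heaviside_eps
#' @return Positive values.
#' @export
dirac_eps <- function(z, epsilon = 1) {
  stopifnot(epsilon > 0)
  (1 / pi) * epsilon / (epsilon^2 + z^2)
}

#' Region means inside and outside the contour
#'
#' `c1` is the H-weighted mean of the image inside the contour (phi > 0
#' side), `c2` the complement-weighted mean outside. Nodata (`NA`) pixels
#' carry zero weight.
#'
#' @param u0 image grid.
#' @param phi level-set surface.
#' @param epsilon Heaviside width.
#' @return Numeric `c(c1, c2)`.
#' @export
region_means <- function(u0, phi, epsilon = 1) {
  h <- heaviside_eps(phi, epsilon)
  ok <- !is.na(u0)
  w1 <- sum(h[ok]); w2 <- sum(1 - h[ok])
  if (w1 <= 0 || w2 <= 0) stop("region_means: a region has zero weight")
  c(sum(u0[ok] * h[ok]) / w1, sum(u0[ok] * (1 - h[ok])) / w2)
}

shift2 <- function(g, dr, dc) {
  # replicate-border shift: entry (i, j) of the result is g(i + dr, j + dc)
  h <- nrow(g); w <- ncol(g)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  g[ri, ci, drop = FALSE]
}

#' Mean curvature of the level-set surface
#'
#' `div(grad(phi) / |grad(phi)|)` by central finite differences with
#' replicate (Neumann) borders; the gradient magnitude in the denominator
#' is regularized by a small `eta` so flat regions return 0 rather than
#' 0/0. For a plane the curvature is 0; for a cone (radial distance) it
#' is 1/r.
#'
#' @param phi level-set grid, at least 3 x 3.
#' @param eta denominator regularization.
#' @return Curvature grid.
#' @export
curvature <- function(phi, eta = 1e-8) {
  stopifnot(nrow(phi) >= 3, ncol(phi) >= 3)
  px <- (shift2(phi, 0L, 1L) - shift2(phi, 0L, -1L)) / 2
  py <- (shift2(phi, 1L, 0L) - shift2(phi, -1L, 0L)) / 2
  pxx <- shift2(phi, 0L, 1L) - 2 * phi + shift2(phi, 0L, -1L)
  pyy <- shift2(phi, 1L, 0L) - 2 * phi + shift2(phi, -1L, 0L)
  pxy <- (shift2(phi, 1L, 1L) - shift2(phi, 1L, -1L) -
          shift2(phi, -1L, 1L) + shift2(phi, -1L, -1L)) / 4
  num <- pxx * py^2 - 2 * px * py * pxy + pyy * px^2
  den <- (px^2 + py^2)^1.5 + eta
  num / den
}

new_levelset_state <- function(phi0) {
  structure(list(phi = phi0, c1 = NA_real_, c2 = NA_real_,
                 iteration = 0L, energy_trace = numeric(0)),
            class = "levelset_state")
}

#' One explicit gradient-descent step of the Chan-Vese evolution
#'
#' Recomputes the region means, then updates
#' `phi <- phi + dt * delta_eps(phi) * (mu*curv - nu - lambda1*(u0-c1)^2
#' + lambda2*(u0-c2)^2)`. Nodata pixels receive no data force. The
#' energy after the step is appended to the trace.
#'
#' @param u0 image grid.
#' @param state a `levelset_state` (from an earlier step, or built
#'   internally by [cv_segment()]).
#' @param params a [cv_params()].
#' @return The updated `levelset_state`.
#' @export
evolve_step <- function(u0, state, params) {
  stopifnot(inherits(params, "cv_params"))
  cc <- region_means(u0, state$phi, params$epsilon)
  force <- params$mu * curvature(state$phi) - params$nu
  data1 <- (u0 - cc[1])^2
  data2 <- (u0 - cc[2])^2
  data1[is.na(data1)] <- 0
  data2[is.na(data2)] <- 0
  force <- force - params$lambda1 * data1 + params$lambda2 * data2
  phi <- state$phi + params$dt * dirac_eps(state$phi, params$epsilon) * force
  if (!all(is.finite(phi)))
    stop("evolve_step: phi became non-finite (time step dt too large)")
  state$phi <- phi
  state$c1 <- cc[1]; state$c2 <- cc[2]
  state$iteration <- state$iteration + 1L
  state$energy_trace <- c(state$energy_trace, cv_energy(u0, phi, params))
  state
}

#' Chan-Vese energy of a level-set configuration
#'
#' The discrete piecewise-constant Mumford-Shah energy
#' `mu*sum(delta_eps(phi)*|grad phi|) + nu*sum(H(phi)) +
#' lambda1*sum((u0-c1)^2*H(phi)) + lambda2*sum((u0-c2)^2*(1-H(phi)))`
#' with the region means `c1, c2` set to their optimal values for the
#' given `phi`.
#'
#' @inheritParams evolve_step
#' @param phi level-set grid.
#' @return Scalar energy.
#' @export
cv_energy <- function(u0, phi, params) {
  cc <- region_means(u0, phi, params$epsilon)
  px <- (shift2(phi, 0L, 1L) - shift2(phi, 0L, -1L)) / 2
  py <- (shift2(phi, 1L, 0L) - shift2(phi, -1L, 0L)) / 2
  gmag <- sqrt(px^2 + py^2)
  h <- heaviside_eps(phi, params$epsilon)
  ok <- !is.na(u0)
  params$mu * sum(dirac_eps(phi, params$epsilon) * gmag) +
    params$nu * sum(h) +
    params$lambda1 * sum((u0[ok] - cc[1])^2 * h[ok]) +
    params$lambda2 * sum((u0[ok] - cc[2])^2 * (1 - h[ok]))
}

#' Segment an image with the Chan-Vese level-set model
#'
#' Evolves `phi` from `phi0` by [evolve_step()] until the fraction of
#' pixels whose sign of phi changed over the last `stop_window`
#' iterations falls below `tol` (with the warm-up and region-contrast
#' guards described in [cv_params()]), or `max_iter` is reached. The returned
#' mask is `phi > 0` (pixels with phi exactly 0 are outside). Because
#' the contour is the zero level of a surface, it splits and merges
#' freely: disjoint objects are recovered from a single connected
#' initialization.
#'
#' The evolution loop runs in compiled code for speed; it reproduces the
#' reference operations [evolve_step()] / [cv_energy()] step for step
#' (asserted by the test suite).
#'
#' @param u0 image grid, expected normalized to \[0, 1\].
#' @param phi0 initial level-set surface with both signs present (e.g.
#'   from [auto_initial_contour()] or [rectangle_initial_contour()]).
#' @param params a [cv_params()].
#' @return An object of class `segmentation_result`: `mask`,
#'   `iterations`, `converged`, `energy_trace`, `flips_trace` (sign
#'   changes per iteration relative to `stop_window` iterations back),
#'   final `phi`, `c1`, `c2`.
#' @export
cv_segment <- function(u0, phi0, params = cv_params()) {
  if (!identical(dim(u0), dim(phi0))) stop("cv_segment: shape mismatch")
  if (all(phi0 <= 0) || all(phi0 >= 0))
    stop("cv_segment: phi0 must contain both signs")
  floor_abs <- 0
  if (params$min_contrast > 0) {
    cls <- tryCatch(otsu_threshold(u0), error = function(e) NULL)
    if (!is.null(cls)) {
      gap <- abs(mean(u0[u0 > cls$threshold], na.rm = TRUE) -
                 mean(u0[u0 <= cls$threshold], na.rm = TRUE))
      if (is.finite(gap)) floor_abs <- params$min_contrast * gap
    }
  }
  res <- .cpp_cv_segment(u0, phi0, params$mu, params$nu, params$lambda1,
                         params$lambda2, params$epsilon, params$dt,
                         params$max_iter, params$tol, params$stop_window,
                         params$min_iter, floor_abs,
                         params$patience, 1e-8)
  structure(list(mask = res$mask, iterations = res$iterations,
                 converged = res$converged, energy_trace = res$energy_trace,
                 flips_trace = res$flips_trace,
                 phi = res$phi, c1 = res$c1, c2 = res$c2),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation> %d x %d, %d inside pixel(s), %d iteration(s)%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$iterations,
              if (x$converged) ", converged" else " (max_iter reached)"))
  invisible(x)
}

#' Write the energy trace of a segmentation as CSV
#'
#' @param x a `segmentation_result`.
#' @param path output CSV path (`iteration, energy`).
#' @return `path`, invisibly.
#' @export
write_energy_trace <- function(x, path) {
  stopifnot(inherits(x, "segmentation_result"))
  utils::write.csv(data.frame(iteration = seq_along(x$energy_trace),
                              energy = x$energy_trace),
                   path, row.names = FALSE)
  invisible(path)
}
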