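#' Least-squares fit of the date-2 NIR band on the date-1 NIR band
#'
#' Pre- and post-fire acquisitions of the same area by the same sensor
#' are highly correlated; pixels that break the fitted linear relation
#' carry the change (burn) signal. An ordinary least-squares line with
#' intercept is fitted and the mean squared residual retained as the
#' residual variance used to scale fitting errors.
#'
#' @param x1,x2 numeric grids (or vectors) of the same shape: date-1 and
#'   date-2 band values.
#' @return An object of class `regression_fit` with `slope`, `intercept`
#'   and `residual_variance`.
#' @export
fit_nir <- function(x1, x2) {
  if (!identical(dim(x1), dim(x2)) || length(x1) != length(x2))
    stop("fit_nir: shape mismatch")
  ok <- !is.na(x1) & !is.na(x2)
  v1 <- as.vector(x1)[ok]; v2 <- as.vector(x2)[ok]
  if (stats::var(v1) == 0) stop("fit_nir: date-1 band is constant")
  fit <- stats::lm(v2 ~ v1)
  res <- stats::residuals(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_variance = mean(res^2)),
            class = "regression_fit")
}

#' Mahalanobis fitting error of the NIR regression
#'
#' Per pixel, the squared residual of the linear fit scaled by the
#' residual variance: `(x2 - slope*x1 - intercept)^2 / s`. Pixels with
#' large error values are the change (burn) candidates. Invariant to
#' jointly rescaling both dates by the same positive constant.
#'
#' @param x1,x2 grids as in [fit_nir()].
#' @param fit a `regression_fit`.
#' @return Non-negative grid of errors.
#' @export
fitting_error <- function(x1, x2, fit) {
  stopifnot(inherits(fit, "regression_fit"))
  scale2 <- stats::var(as.vector(x2)[!is.na(x2)])
  if (fit$residual_variance <= 1e-12 * max(scale2, .Machine$double.eps))
    stop("fitting_error: (near-)zero residual variance - the two dates are ",
         "an exact linear map of each other (no-change scene)")
  (x2 - fit$slope * x1 - fit$intercept)^2 / fit$residual_variance
}

#' Two-cluster split of 1-D values
#'
#' Partitions a list of real values into two clusters minimizing the
#' within-cluster sum of squares. In one dimension with two clusters the
#' K-means optimum is a threshold partition, so the global optimum is
#' found exactly by scanning the n-1 contiguous splits of the sorted
#' values; the result is deterministic and independent of the seed
#' (kept in the signature for interface stability).
#'
#' @param values numeric vector with at least two distinct values.
#' @param seed unused; the exact solver has no random state.
#' @return List with `labels` (1 = lower-center cluster, 2 = higher) and
#'   `centers` (ascending).
#' @export
kmeans_split <- function(values, seed = 0L) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("kmeans_split: NA values")
  n <- length(values)
  if (n < 2L || length(unique(values)) < 2L)
    stop("kmeans_split: need at least two distinct values")
  o <- order(values)
  s <- values[o]
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)
  # within-cluster SSE of split after position k, via prefix sums
  sse <- (cs2[k] - cs[k]^2 / k) +
         ((cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k))
  # splits between tied values are equivalent; take the first minimum
  kbest <- which.min(sse)
  thr <- s[kbest]                       # values <= thr go to the lower cluster
  labels <- ifelse(values <= thr, 1L, 2L)
  centers <- c(mean(values[labels == 1L]), mean(values[labels == 2L]))
  list(labels = labels, centers = centers)
}

as_initial_contour <- function(mask, source, c = 2) {
  mask <- (mask > 0) * 1L
  structure(list(mask = mask, phi0 = ifelse(mask == 1L, c, -c), source = source),
            class = "initial_contour")
}

#' @export
print.initial_contour <- function(x, ...) {
  cat(sprintf("<initial_contour> %d x %d, %s, %d inside pixel(s)\n",
              nrow(x$mask), ncol(x$mask), x$source, sum(x$mask)))
  invisible(x)
}

#' Automatic initial contour from NIR fitting errors
#'
#' Regresses the date-2 NIR band on the date-1 NIR band, computes the
#' Mahalanobis fitting error per pixel, splits the errors into two
#' clusters with [kmeans_split()], and takes the higher-center cluster as
#' the change mask. The level-set surface is a binary step: `phi0 = +2`
#' on the mask and `-2` elsewhere (the regularized Chan-Vese update does
#' not require a signed-distance function).
#'
#' @param pre,post co-registered [scene()]s sharing the NIR role.
#' @param seed forwarded to [kmeans_split()] (no effect; exact solver).
#' @return An `initial_contour` with `source = "auto"`.
#' @export
auto_initial_contour <- function(pre, post, seed = 0L) {
  x1 <- scene_band(pre, "nir")
  x2 <- scene_band(post, "nir")
  fit <- fit_nir(x1, x2)
  err <- fitting_error(x1, x2, fit)
  ok <- !is.na(err)
  split <- kmeans_split(err[ok], seed)
  mask <- matrix(0L, nrow(err), ncol(err))
  mask[ok][split$labels == 2L] <- 1L
  as_initial_contour(mask, "auto")
}

#' Tiled-rectangle initial contour (traditional initialization)
#'
#' The traditional Chan-Vese starting curve: a periodic grid of
#' rectangles filling the whole image, one rectangle per `spacing x
#' spacing` cell with a one-pixel gap between rectangles.
#'
#' @param shape integer `(h, w)`.
#' @param spacing cell period in pixels, at least 4 and smaller than both
#'   image dimensions.
#' @return An `initial_contour` with `source = "rectangles"`.
#' @export
rectangle_initial_contour <- function(shape, spacing = 16L) {
  h <- shape[1]; w <- shape[2]
  spacing <- as.integer(spacing)
  if (spacing < 4L || spacing >= h || spacing >= w)
    stop("rectangle_initial_contour: spacing must be >= 4 and smaller than both dimensions")
  ri <- (seq_len(h) - 1L) %% spacing
  ci <- (seq_len(w) - 1L) %% spacing
  inside_r <- ri >= 1L & ri <= spacing - 2L
  inside_c <- ci >= 1L & ci <= spacing - 2L
  mask <- outer(inside_r, inside_c, `&`) * 1L
  as_initial_contour(mask, "rectangles")
}
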