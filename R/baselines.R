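#' Otsu thresholding of a difference grid
#'
#' The grid is min-max normalized and binned into 256 equal-width bins;
#' the returned threshold maximizes the between-class variance
#' `w0*w1*(mu0 - mu1)^2` over all bin boundaries (first maximum on
#' ties). The mask is `g > threshold` on the original scale, so it is
#' invariant to affine rescaling of `g`.
#'
#' @param g numeric grid with at least two distinct values.
#' @param bins histogram resolution.
#' @return List with `threshold` (original scale) and `mask` (0/1 grid,
#'   `NA` pixels map to 0).
#' @export
otsu_threshold <- function(g, bins = 256L) {
  v <- as.vector(g)
  v <- v[!is.na(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("otsu_threshold: constant grid")
  x <- (v - lo) / (hi - lo)
  counts <- tabulate(pmin(findInterval(x, seq(0, 1, length.out = bins + 1L),
                                       rightmost.closed = TRUE), bins), bins)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  n <- w0[bins]; mtot <- m0[bins]
  k <- seq_len(bins - 1L)
  w1 <- n - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (w0[k][valid] / n) * (w1[valid] / n) *
    (m0[k][valid] / w0[k][valid] - (mtot - m0[k][valid]) / w1[valid])^2
  kbest <- which.max(bcv)
  thr_norm <- kbest / bins               # boundary between bins kbest and kbest+1
  thr <- lo + thr_norm * (hi - lo)
  mask <- (g > thr)
  mask[is.na(mask)] <- FALSE
  list(threshold = thr, mask = mask * 1L)
}

#' Fuzzy C-means parameters
#'
#' @param m fuzzifier, > 1.
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed kept for interface stability; clustering is made
#'   deterministic by quantile-based initial centers.
#' @return An object of class `fcm_params`.
#' @export
fcm_params <- function(m = 2, tol = 1e-5, max_iter = 300L, seed = 0L) {
  stopifnot(m > 1, tol > 0, max_iter >= 1)
  structure(list(m = m, tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)), class = "fcm_params")
}

#' Fuzzy C-means segmentation of a difference grid
#'
#' Two-cluster fuzzy C-means on pixel intensities (via
#' \code{e1071::cmeans}), initialized at the 25% and 75% intensity
#' quantiles so the result is deterministic. The mask is the set of
#' pixels whose membership in the higher-center cluster exceeds 0.5.
#'
#' @param g numeric grid with at least two distinct values.
#' @param params an [fcm_params()].
#' @return 0/1 mask grid (`NA` pixels map to 0), with the cluster centers
#'   attached as attribute `"centers"`.
#' @export
fcm_segment <- function(g, params = fcm_params()) {
  stopifnot(inherits(params, "fcm_params"))
  v <- as.vector(g)
  ok <- !is.na(v)
  x <- v[ok]
  if (length(unique(x)) < 2L) stop("fcm_segment: constant grid")
  init <- matrix(stats::quantile(x, c(0.25, 0.75), names = FALSE), ncol = 1)
  if (init[1] == init[2]) init <- matrix(range(x), ncol = 1)
  cm <- e1071::cmeans(matrix(x, ncol = 1), centers = init,
                      iter.max = params$max_iter, m = params$m,
                      method = "cmeans")
  hi <- which.max(cm$centers[, 1])
  mask_v <- rep(0L, length(v))
  mask_v[ok] <- (cm$membership[, hi] > 0.5) * 1L
  mask <- matrix(mask_v, nrow(g), ncol(g))
  attr(mask, "centers") <- sort(cm$centers[, 1])
  mask
}

orient_burn_mask <- function(mask, g) {
  # burned change is bright in the difference image; flip the labeling if the
  # level-set happened to converge with the dark class inside
  inside <- mean(g[mask == 1L], na.rm = TRUE)
  outside <- mean(g[mask == 0L], na.rm = TRUE)
  if (is.finite(inside) && is.finite(outside) && inside < outside)
    mask <- 1L - mask
  mask
}

#' Traditional Chan-Vese baseline (TCV)
#'
#' The conventional configuration: the difference image is the min-max
#' normalized CVA magnitude alone (no index fusion) and the initial
#' contour is the tiled-rectangle pattern. The final mask is oriented so
#' that the burn class is the brighter one in the difference grid.
#'
#' @param pre,post co-registered [scene()]s.
#' @param params a [cv_params()].
#' @param spacing rectangle period for [rectangle_initial_contour()].
#' @return A `segmentation_result` (mask oriented burn = 1).
#' @export
tcv_segment <- function(pre, post, params = cv_params(), spacing = 16L) {
  di <- minmax_normalize(cva_magnitude(pre, post))
  init <- rectangle_initial_contour(dim(di), spacing)
  res <- cv_segment(di, init$phi0, params)
  res$mask <- orient_burn_mask(res$mask, di)
  res
}
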