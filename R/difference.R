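#' Change vector analysis magnitude
#'
#' Per-pixel Euclidean norm of the spectral difference vector between the
#' two dates over the configured CVA bands. Large magnitudes mean a high
#' probability that the pixel changed.
#'
#' @param pre,post co-registered [scene()]s of the same shape with
#'   identical `cva_bands`.
#' @return Non-negative matrix; `NA` where any contributing band is nodata.
#' @export
cva_magnitude <- function(pre, post) {
  stopifnot(inherits(pre, "scene"), inherits(post, "scene"))
  if (!identical(dim(pre$pixels), dim(post$pixels)))
    stop("cva_magnitude: scenes differ in shape")
  bands <- pre$roles$cva_bands
  if (!identical(bands, post$roles$cva_bands))
    stop("cva_magnitude: cva_bands differ between dates")
  if (length(bands) == 0L) stop("cva_magnitude: empty cva_bands")
  acc <- 0
  for (b in bands) acc <- acc + (post$pixels[, , b] - pre$pixels[, , b])^2
  sqrt(acc)
}

norm_ratio <- function(a, b) {
  s <- a + b
  r <- ifelse(abs(s) > 0, (a - b) / s, 0)
  pmin(pmax(r, -1), 1)
}

#' Normalized difference vegetation index
#'
#' `(NIR - red) / (NIR + red)`, clipped to \[-1, 1\]; pixels with a zero
#' denominator map to 0. Healthy vegetation is high; fire-destroyed
#' vegetation drops.
#'
#' @param x a [scene()].
#' @return Matrix in \[-1, 1\].
#' @export
ndvi <- function(x) norm_ratio(scene_band(x, "nir"), scene_band(x, "red"))

#' Normalized burn ratio
#'
#' `(NIR - midIR) / (NIR + midIR)`, the red band of NDVI replaced by the
#' mid-infrared band, which is sensitive to vegetation water and lignose
#' content; same guards as [ndvi()].
#'
#' @param x a [scene()].
#' @return Matrix in \[-1, 1\].
#' @export
nbr <- function(x) norm_ratio(scene_band(x, "nir"), scene_band(x, "mir"))

#' Pre-minus-post index difference
#'
#' Computed as `pre - post`, so a vegetation index that falls after the
#' fire yields a positive change — the standard dNBR orientation, and the
#' orientation under which burned pixels are bright in the difference
#' image.
#'
#' @param pre_index,post_index index grids of the same shape.
#' @return Matrix of differences.
#' @export
index_difference <- function(pre_index, post_index) {
  if (!identical(dim(pre_index), dim(post_index)))
    stop("index_difference: shape mismatch")
  pre_index - post_index
}

#' Min-max normalization to \[0, 1\]
#'
#' `(g - min) / (max - min)` over valid (non-`NA`) pixels; a constant grid
#' maps to all zeros. `NA` pixels stay `NA`.
#'
#' @param g numeric matrix.
#' @return Matrix in \[0, 1\].
#' @export
minmax_normalize <- function(g) {
  lo <- min(g, na.rm = TRUE)
  hi <- max(g, na.rm = TRUE)
  if (hi > lo) (g - lo) / (hi - lo) else g * 0
}

#' Fuse normalized difference components into the difference image
#'
#' Weighted fusion of the three normalized change features: each
#' component's weight is its standard deviation over valid pixels,
#' normalized so the weights sum to 1; the weighted sum is then min-max
#' rescaled to \[0, 1\]. Components with no variation get weight 0; if no
#' component varies there is no change signal and an error is raised.
#'
#' @param d_cva,d_ndvi,d_nbr component grids, min-max normalized to
#'   \[0, 1\], same shape.
#' @return An object of class `difference_product` with fields `di`
#'   (fused grid in \[0, 1\]), `components` (named list of the three
#'   inputs) and `weights` (named, summing to 1).
#' @export
fuse_differences <- function(d_cva, d_ndvi, d_nbr) {
  comps <- list(cva = d_cva, ndvi = d_ndvi, nbr = d_nbr)
  d <- dim(d_cva)
  if (!identical(dim(d_ndvi), d) || !identical(dim(d_nbr), d))
    stop("fuse_differences: components differ in shape")
  sds <- vapply(comps, function(g) stats::sd(as.vector(g), na.rm = TRUE), 0)
  if (all(sds == 0))
    stop("fuse_differences: all components constant - no change signal")
  w <- sds / sum(sds)
  di <- w[1] * d_cva + w[2] * d_ndvi + w[3] * d_nbr
  structure(list(di = minmax_normalize(di), components = comps, weights = w),
            class = "difference_product")
}

#' @export
print.difference_product <- function(x, ...) {
  cat(sprintf("<difference_product> %d x %d, weights cva=%.3f ndvi=%.3f nbr=%.3f\n",
              nrow(x$di), ncol(x$di), x$weights[1], x$weights[2], x$weights[3]))
  invisible(x)
}

#' Class-separability diagnostics of a difference image
#'
#' The normalized distance `D = |mean_burn - mean_unburn| / (sd_burn +
#' sd_unburn)` between the burn and unburn intensity distributions, plus
#' per-class histograms on a shared fixed bin grid over \[0, 1\] and their
#' overlap fraction (sum over bins of the pointwise minimum of the two
#' class proportions). A larger D — equivalently a smaller overlap —
#' means the difference image discriminates burn from unburn better.
#'
#' @param di difference grid (expected in \[0, 1\]).
#' @param truth binary ground-truth grid, 1 = burn.
#' @param bins number of equal-width histogram bins on \[0, 1\].
#' @return An object of class `separability_report`.
#' @export
separability <- function(di, truth, bins = 64L) {
  if (!identical(dim(di), dim(truth))) stop("separability: shape mismatch")
  ok <- !is.na(di) & !is.na(truth)
  b <- di[ok & truth == 1]
  u <- di[ok & truth == 0]
  if (length(b) == 0 || length(u) == 0)
    stop("separability: a class is empty")
  mb <- mean(b); mu <- mean(u)
  sb <- stats::sd(b); su <- stats::sd(u)
  if (length(b) == 1) sb <- 0
  if (length(u) == 1) su <- 0
  if (sb + su == 0) stop("separability: both class SDs are zero")
  brk <- seq(0, 1, length.out = bins + 1L)
  cut_counts <- function(v) {
    v <- pmin(pmax(v, 0), 1)
    tabulate(pmin(findInterval(v, brk, rightmost.closed = TRUE), bins), bins)
  }
  hb <- cut_counts(b); hu <- cut_counts(u)
  overlap <- sum(pmin(hb / length(b), hu / length(u)))
  structure(list(d_value = abs(mb - mu) / (sb + su),
                 burn_mean = mb, unburn_mean = mu,
                 burn_sd = sb, unburn_sd = su,
                 bin_left = brk[-length(brk)],
                 burn_count = hb, unburn_count = hu,
                 overlap_fraction = overlap),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("<separability> D = %.4f (burn %.3f+/-%.3f, unburn %.3f+/-%.3f), overlap = %.3f\n",
              x$d_value, x$burn_mean, x$burn_sd, x$unburn_mean, x$unburn_sd,
              x$overlap_fraction))
  invisible(x)
}

#' Serialize a separability report
#'
#' @param x a [separability()] report.
#' @param json_path optional path for a JSON dump of the scalar fields.
#' @param csv_path optional path for the histogram as CSV
#'   (`bin_left, burn_count, unburn_count`).
#' @return `x`, invisibly.
#' @export
write_separability <- function(x, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(x, "separability_report"))
  if (!is.null(json_path))
    jsonlite::write_json(
      x[c("d_value", "burn_mean", "unburn_mean", "burn_sd", "unburn_sd",
          "overlap_fraction")],
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(data.frame(bin_left = x$bin_left,
                                burn_count = x$burn_count,
                                unburn_count = x$unburn_count),
                     csv_path, row.names = FALSE)
  invisible(x)
}

#' Build the fused difference image for a bi-temporal pair
#'
#' Convenience wrapper running the whole fusion branch: CVA magnitude,
#' NDVI difference and NBR difference, each min-max normalized, then
#' SD-weighted fusion via [fuse_differences()].
#'
#' @param pre,post co-registered [scene()]s.
#' @return A `difference_product`.
#' @export
difference_image <- function(pre, post) {
  fuse_differences(
    minmax_normalize(cva_magnitude(pre, post)),
    minmax_normalize(index_difference(ndvi(pre), ndvi(post))),
    minmax_normalize(index_difference(nbr(pre), nbr(post))))
}
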