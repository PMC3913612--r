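#' Confusion counts for a burn mask against ground truth
#'
#' Burn is the positive class. Pixels that are `NA` in either grid
#' (nodata) are excluded, so `tp + fn + fp + tn` equals the number of
#' valid pixels.
#'
#' @param pred,truth 0/1 grids of the same shape.
#' @return An object of class `confusion_counts` with `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("confusion_counts: shape mismatch")
  ok <- !is.na(pred) & !is.na(truth)
  p <- pred[ok]; t <- truth[ok]
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("confusion_counts: masks must be 0/1")
  structure(list(tp = sum(p == 1 & t == 1), fn = sum(p == 0 & t == 1),
                 fp = sum(p == 1 & t == 0), tn = sum(p == 0 & t == 0)),
            class = "confusion_counts")
}

#' Missed, false and right alarm rates
#'
#' All three are percentages of the total valid pixel count, so they sum
#' to exactly 100: missed = `100*fn/N` (burn classified unburn), false =
#' `100*fp/N` (unburn classified burn), right = `100*(tp+tn)/N`.
#'
#' @param c a [confusion_counts()].
#' @return Named numeric `c(missed_pct, false_pct, right_pct)`.
#' @export
alarm_rates <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fn + c$fp + c$tn
  if (n == 0) stop("alarm_rates: empty confusion")
  c(missed_pct = 100 * c$fn / n,
    false_pct = 100 * c$fp / n,
    right_pct = 100 * (c$tp + c$tn) / n)
}

#' Cohen's kappa of a confusion
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp + tn)/N` and expected agreement `p_e` from the
#' marginal products.
#'
#' @param c a [confusion_counts()].
#' @return Scalar in \[-1, 1\].
#' @export
kappa_coefficient <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fn + c$fp + c$tn
  if (n == 0) stop("kappa_coefficient: empty confusion")
  po <- (c$tp + c$tn) / n
  pe <- ((c$tp + c$fp) / n) * ((c$tp + c$fn) / n) +
        ((c$tn + c$fn) / n) * ((c$tn + c$fp) / n)
  if (pe == 1) stop("kappa_coefficient: degenerate marginals (p_e = 1)")
  (po - pe) / (1 - pe)
}

#' One-row accuracy report for a predicted mask
#'
#' @param pred,truth 0/1 grids.
#' @param method label for the row.
#' @param iterations iteration count for level-set methods, `NA`
#'   otherwise.
#' @return A one-row data.frame: `method`, `missed_pct`, `false_pct`,
#'   `right_pct`, `kappa`, `iterations`.
#' @export
eval_report <- function(pred, truth, method = "method", iterations = NA_integer_) {
  cc <- confusion_counts(pred, truth)
  r <- alarm_rates(cc)
  data.frame(method = method,
             missed_pct = r[["missed_pct"]], false_pct = r[["false_pct"]],
             right_pct = r[["right_pct"]], kappa = kappa_coefficient(cc),
             iterations = as.integer(iterations),
             stringsAsFactors = FALSE)
}

#' Run and score all four extraction methods on one scene pair
#'
#' Reruns the proposed pipeline (fused difference image + automatic
#' initial contour + Chan-Vese), Otsu and fuzzy C-means on the fused
#' difference image, and the traditional Chan-Vese baseline (CVA
#' difference image + rectangle initialization) against one ground-truth
#' mask, producing a method-comparison table (one accuracy row per
#' method; iteration counts for the level-set methods only).
#'
#' @param pre,post co-registered [scene()]s.
#' @param truth 0/1 ground-truth grid.
#' @param cv a [cv_params()].
#' @param fcm an [fcm_params()].
#' @param spacing rectangle period of the TCV initialization.
#' @param seed forwarded to the initialization (kept for interface
#'   stability; the pipeline is deterministic).
#' @return A 4-row data.frame as in [eval_report()], methods
#'   `proposed`, `otsu`, `fcm`, `tcv`.
#' @export
compare_methods <- function(pre, post, truth, cv = cv_params(),
                            fcm = fcm_params(), spacing = 16L, seed = 0L) {
  dp <- difference_image(pre, post)
  prop <- extract_burn_scar(pre, post, method = "proposed", cv = cv,
                            seed = seed, di = dp)
  ots <- otsu_threshold(dp$di)
  fcm_mask <- fcm_segment(dp$di, fcm)
  tcv <- tcv_segment(pre, post, cv, spacing)
  rbind(
    eval_report(prop$mask, truth, "proposed", prop$segmentation$iterations),
    eval_report(ots$mask, truth, "otsu"),
    eval_report(fcm_mask, truth, "fcm"),
    eval_report(tcv$mask, truth, "tcv", tcv$iterations))
}
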