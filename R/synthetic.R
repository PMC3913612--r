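#' Separable Gaussian smoothing with replicate borders
#'
#' Small utility used by the scene generator (random-field class maps and
#' scar shapes, soft scar edges). Kernel radius is `ceiling(3*sigma)`.
#'
#' @param g numeric matrix.
#' @param sigma Gaussian SD in pixels; 0 returns `g` unchanged.
#' @return Smoothed matrix of the same shape.
#' @export
gauss_smooth <- function(g, sigma) {
  if (sigma <= 0) return(g)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  out <- 0
  for (k in -r:r) out <- out + w[k + r + 1L] * shift2(g, k, 0L)
  g2 <- out
  out <- 0
  for (k in -r:r) out <- out + w[k + r + 1L] * shift2(g2, 0L, k)
  out
}

#' Specification of a synthetic bi-temporal burn scene
#'
#' Defines the study conditions the generator emulates: a vegetated/soil
#' background with per-class, per-band spectra on a digital-number-like
#' scale; an irregular, possibly concave burn region with blurred edges;
#' post-fire spectral shifts (near-infrared strongly down, red and
#' mid-infrared up, other bands mildly up); and temporal noise in
#' unburned areas. Bands follow the TM-like stacking of
#' [band_roles()]`("tm")`: planes 1..6 = blue, green, red, NIR, SWIR1,
#' SWIR2.
#'
#' @param shape integer `(h, w)`.
#' @param class_spectra list of two classes (`veg`, `soil`), each with
#'   numeric `mean` and `sd` per band (pre-fire digital numbers).
#' @param burn_shift per-band additive change inside the burn region.
#' @param temporal_noise_sd per-band (or scalar) SD of date-2 noise,
#'   applied everywhere.
#' @param gain_sd,offset_sd SDs of the per-band radiometric drift between
#'   the two acquisitions: date-2 band values are `gain * pre + offset`
#'   before the burn shift and noise, with `gain ~ N(1, gain_sd)` and
#'   `offset ~ N(0, offset_sd)` drawn once per band. Illumination and
#'   atmospheric differences of this kind inflate the raw band
#'   differences seen by change vector analysis while largely cancelling
#'   in the normalized indices — and are what the NIR-on-NIR regression
#'   of the automatic initialization absorbs.
#' @param scar_smoothness Gaussian SD (pixels) of the scar edge blur
#'   applied to the spectral shift (the ground-truth mask stays binary).
#' @param scar_area_fraction target burn fraction of the image, in
#'   (0, 0.5).
#' @param n_components number of disjoint burn blobs (1 by default; more
#'   for topology tests).
#' @param seed integer RNG seed; the generated pair is fully
#'   deterministic given the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(128L, 128L),
                       class_spectra = list(
                         veg  = list(mean = c(55, 50, 40, 120, 80, 40), sd = rep(4, 6)),
                         soil = list(mean = c(70, 65, 70, 90, 110, 85), sd = rep(4, 6))),
                       burn_shift = c(5, 5, 15, -50, 10, 25),
                       temporal_noise_sd = 3,
                       gain_sd = 0.03,
                       offset_sd = 2,
                       scar_smoothness = 1,
                       scar_area_fraction = 0.15,
                       n_components = 1L,
                       seed = 0L) {
  nb <- length(burn_shift)
  stopifnot(length(shape) == 2L, all(shape >= 16L),
            length(class_spectra) == 2L,
            all(vapply(class_spectra, function(cl)
              length(cl$mean) == nb && length(cl$sd) == nb && all(cl$sd >= 0),
              TRUE)),
            scar_area_fraction > 0, scar_area_fraction < 0.5,
            scar_smoothness >= 0, n_components >= 1L,
            gain_sd >= 0, offset_sd >= 0,
            all(temporal_noise_sd >= 0))
  if (length(temporal_noise_sd) == 1L)
    temporal_noise_sd <- rep(temporal_noise_sd, nb)
  stopifnot(length(temporal_noise_sd) == nb)
  structure(list(shape = as.integer(shape), n_bands = nb,
                 class_spectra = class_spectra, burn_shift = burn_shift,
                 temporal_noise_sd = temporal_noise_sd,
                 gain_sd = gain_sd, offset_sd = offset_sd,
                 scar_smoothness = scar_smoothness,
                 scar_area_fraction = scar_area_fraction,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# draw a smoothed Gaussian random field and threshold it so that the union of
# the n largest connected components hits the target area (bisection on the
# quantile level); NULL when this field cannot satisfy the target
scar_from_field <- function(shape, target_px, n_components, tol = 0.1) {
  field <- gauss_smooth(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                        sigma = min(shape) / 8)
  top_mask <- function(q) {
    m <- field >= stats::quantile(field, q)
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    if (length(sizes) < n_components) return(NULL)
    keep <- order(sizes, decreasing = TRUE)[seq_len(n_components)]
    (matrix(lab, shape[1], shape[2]) %in% keep) * 1L
  }
  lo <- 0.5; hi <- 0.995
  best <- NULL; best_err <- Inf
  for (i in 1:30) {
    q <- (lo + hi) / 2
    m <- top_mask(q)
    a <- if (is.null(m)) 0 else sum(m)
    err <- abs(a - target_px) / target_px
    if (err < best_err && !is.null(m)) { best <- m; best_err <- err }
    if (a > target_px) lo <- q else hi <- q
  }
  if (best_err <= tol) matrix(best, shape[1], shape[2]) else NULL
}

#' Generate a synthetic bi-temporal burn-scene pair
#'
#' Produces a pre-fire scene (vegetation/soil patch background plus
#' per-band Gaussian texture), a binary ground-truth burn mask (a
#' thresholded smoothed Gaussian random field, giving an irregular and
#' possibly concave blob), and a post-fire scene obtained by adding the
#' per-band `burn_shift` modulated by a blurred copy of the mask (so the
#' imaged scar has soft edges) plus temporal noise everywhere.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return List with `pre` and `post` ([scene()]s with TM-like roles) and
#'   `truth` (0/1 matrix).
#' @export
make_burn_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$shape[1]; w <- spec$shape[2]; nb <- spec$n_bands
    cls_field <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), min(h, w) / 8)
    is_veg <- cls_field <= stats::median(cls_field)
    target_px <- spec$scar_area_fraction * h * w
    truth <- NULL
    for (try in 1:100) {
      truth <- scar_from_field(c(h, w), target_px, spec$n_components)
      if (!is.null(truth)) break
    }
    if (is.null(truth))
      stop("make_burn_pair: could not satisfy scar_area_fraction after 100 field redraws")
    soft <- gauss_smooth(truth + 0, spec$scar_smoothness)
    gains <- stats::rnorm(nb, mean = 1, sd = spec$gain_sd)
    offsets <- stats::rnorm(nb, mean = 0, sd = spec$offset_sd)
    pre_px <- post_px <- array(NA_real_, c(h, w, nb))
    for (b in seq_len(nb)) {
      mu <- ifelse(is_veg, spec$class_spectra$veg$mean[b],
                   spec$class_spectra$soil$mean[b])
      sd_b <- ifelse(is_veg, spec$class_spectra$veg$sd[b],
                     spec$class_spectra$soil$sd[b])
      pre_px[, , b] <- mu + stats::rnorm(h * w, sd = sd_b)
      post_px[, , b] <- gains[b] * pre_px[, , b] + offsets[b] +
        spec$burn_shift[b] * soft +
        stats::rnorm(h * w, sd = spec$temporal_noise_sd[b])
    }
    roles <- band_roles("tm")
    list(pre = scene(pre_px, roles), post = scene(post_px, roles),
         truth = truth)
  })
}

#' Noisy two-value disk image (unit fixture for the level-set solver)
#'
#' @param shape integer `(h, w)`.
#' @param inside_value,outside_value distinct intensities.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @param radius disk radius in pixels (default `min(shape)/4`).
#' @param center disk center `(row, col)` (default image center).
#' @return List with `image` (matrix) and `truth` (0/1 matrix).
#' @export
make_disk_image <- function(shape = c(64L, 64L), inside_value = 0.8,
                            outside_value = 0.2, noise_sd = 0.02, seed = 0L,
                            radius = NULL, center = NULL) {
  stopifnot(inside_value != outside_value)
  h <- shape[1]; w <- shape[2]
  radius <- radius %||% (min(h, w) / 4)
  center <- center %||% c((h + 1) / 2, (w + 1) / 2)
  rr <- outer(seq_len(h) - center[1], rep(1, w))
  cc <- outer(rep(1, h), seq_len(w) - center[2])
  truth <- (sqrt(rr^2 + cc^2) <= radius) * 1L
  img <- ifelse(truth == 1L, inside_value, outside_value)
  if (noise_sd > 0)
    img <- with_seed(seed, img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w))
  list(image = img, truth = truth)
}
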