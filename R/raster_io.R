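#' Band-role presets and custom band maps
#'
#' Maps the semantic band roles needed by the spectral indices (red,
#' near-infrared, mid-infrared) and by change vector analysis onto plane
#' indices of a raster stack. Two presets are built in:
#'
#' * `"tm"` — a Landsat 5 TM reflective stack stored as planes 1..6 =
#'   TM bands 1, 2, 3, 4, 5, 7: red = plane 3 (band 3), NIR = plane 4
#'   (band 4), mid-IR = plane 6 (band 7), CVA over all six planes.
#' * `"oli"` — a Landsat 8 OLI reflective stack stored as planes 1..6 =
#'   OLI bands 2..7: red = plane 3 (band 4), NIR = plane 4 (band 5),
#'   mid-IR = plane 6 (band 7), CVA over all six planes.
#'
#' The normalized burn ratio conventionally pairs NIR with SWIR2
#' (TM/OLI band 7); pass `mir` explicitly to use SWIR1 instead.
#'
#' @param sensor `"tm"`, `"oli"` or `"custom"`.
#' @param red,nir,mir 1-based plane indices (required for `"custom"`,
#'   override the preset otherwise).
#' @param cva_bands integer vector of plane indices used by CVA.
#' @return An object of class `band_roles`.
#' @export
band_roles <- function(sensor = c("tm", "oli", "custom"),
                       red = NULL, nir = NULL, mir = NULL, cva_bands = NULL) {
  sensor <- match.arg(sensor)
  preset <- switch(sensor,
    tm     = list(red = 3L, nir = 4L, mir = 6L, cva_bands = 1:6),
    oli    = list(red = 3L, nir = 4L, mir = 6L, cva_bands = 1:6),
    custom = list(red = NULL, nir = NULL, mir = NULL, cva_bands = NULL))
  roles <- list(
    red = as.integer(red %||% preset$red),
    nir = as.integer(nir %||% preset$nir),
    mir = as.integer(mir %||% preset$mir),
    cva_bands = as.integer(cva_bands %||% preset$cva_bands),
    sensor = sensor)
  if (length(roles$red) != 1L || length(roles$nir) != 1L || length(roles$mir) != 1L)
    stop("band_roles: red, nir and mir must each be a single plane index")
  if (length(roles$cva_bands) < 1L)
    stop("band_roles: cva_bands must name at least one plane")
  if (anyDuplicated(c(roles$red, roles$nir, roles$mir)))
    stop("band_roles: red, nir and mir must be distinct planes")
  structure(roles, class = "band_roles")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a multiband scene
#'
#' A scene is one acquisition date: an `h x w x bands` array of per-band
#' values (digital numbers or reflectance — the downstream math is
#' scale-covariant after normalization), the band-role map, an optional
#' nodata value (converted to `NA` on construction so that nodata pixels
#' are excluded from every downstream statistic), and an optional opaque
#' georeference carried through to outputs.
#'
#' @param pixels numeric array `h x w x bands` (a matrix is promoted to a
#'   single-band array).
#' @param roles a [band_roles()] object.
#' @param nodata_value optional scalar flagged as missing.
#' @param georef optional list (geotransform, CRS, ...) carried opaquely.
#' @return An object of class `scene`.
#' @export
scene <- function(pixels, roles, nodata_value = NULL, georef = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  nb <- dim(pixels)[3]
  idx <- c(roles$red, roles$nir, roles$mir, roles$cva_bands)
  if (any(idx < 1L | idx > nb))
    stop(sprintf("band role index out of range: raster has %d band(s)", nb))
  if (!is.null(nodata_value)) pixels[pixels == nodata_value] <- NA_real_
  structure(list(pixels = pixels, roles = roles,
                 nodata_value = nodata_value, georef = georef),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scene> %d x %d pixels, %d band(s) [%s]%s\n", d[1], d[2], d[3],
              x$roles$sensor,
              if (is.null(x$georef)) "" else ", georeferenced"))
  invisible(x)
}

#' @export
dim.scene <- function(x) dim(x$pixels)

#' Extract one band of a scene by semantic role
#'
#' @param x a [scene()].
#' @param role `"red"`, `"nir"` or `"mir"`, or a plane index.
#' @return A numeric matrix.
#' @export
scene_band <- function(x, role) {
  stopifnot(inherits(x, "scene"))
  i <- if (is.character(role)) x$roles[[match.arg(role, c("red", "nir", "mir"))]]
       else as.integer(role)
  matrix(x$pixels[, , i], dim(x$pixels)[1], dim(x$pixels)[2])
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a multiband scene to disk
#'
#' Bands are stored as pages of a 32-bit-float TIFF. Because the TIFF
#' writer stores values in \[0, 1\], each band is min-max scaled on write
#' and the per-band ranges — together with the nodata value and the
#' georeference — are recorded in a JSON sidecar (`<path>.aux.json`) and
#' restored on read. Real-valued round trips are exact to within float32
#' precision (relative error < 1e-6).
#'
#' @param x a [scene()].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_scene <- function(x, path) {
  stopifnot(inherits(x, "scene"))
  px <- x$pixels
  nb <- dim(px)[3]
  lo <- hi <- numeric(nb)
  pages <- vector("list", nb)
  for (b in seq_len(nb)) {
    g <- px[, , b]
    na <- is.na(g)
    lo[b] <- suppressWarnings(min(g, na.rm = TRUE))
    hi[b] <- suppressWarnings(max(g, na.rm = TRUE))
    if (!is.finite(lo[b])) { lo[b] <- 0; hi[b] <- 1 }      # all-nodata band
    rng <- hi[b] - lo[b]
    g <- if (rng > 0) (g - lo[b]) / rng else g * 0
    g[na] <- 0                                              # placeholder; mask in sidecar
    pages[[b]] <- g
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  aux <- list(kind = "scene", band_min = lo, band_max = hi,
              nodata_value = x$nodata_value, georef = x$georef,
              nodata_mask_page = NA)
  if (anyNA(px)) {
    # nodata locations as an extra mask file alongside
    mask <- apply(is.na(px), c(1, 2), any) * 1
    tiff::writeTIFF(mask, paste0(path, ".nodata.tif"), bits.per.sample = 8L,
                    compression = "none")
    aux$nodata_mask_page <- basename(paste0(path, ".nodata.tif"))
  }
  jsonlite::write_json(aux, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multiband scene from disk
#'
#' Reads a raster written by [write_scene()] (or any multi-page TIFF, in
#' which case values are taken as stored in \[0, 1\]) and attaches the
#' band-role map.
#'
#' @param path raster path.
#' @param roles a [band_roles()] object; indices are validated against the
#'   file's band count.
#' @return A [scene()].
#' @export
read_scene <- function(path, roles) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  px <- array(NA_real_, c(h, w, length(pages)))
  aux <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else NULL
  for (b in seq_along(pages)) {
    g <- pages[[b]]
    if (!is.null(aux)) {
      rng <- aux$band_max[b] - aux$band_min[b]
      g <- if (rng > 0) g * rng + aux$band_min[b] else g + aux$band_min[b]
    }
    px[, , b] <- g
  }
  if (!is.null(aux) && length(aux$nodata_mask_page) == 1 &&
      !is.na(aux$nodata_mask_page) && is.character(aux$nodata_mask_page)) {
    nd <- tiff::readTIFF(file.path(dirname(path), aux$nodata_mask_page))
    px[array(rep(nd > 0.5, length(pages)), dim(px))] <- NA_real_
  }
  georef <- if (!is.null(aux)) aux$georef else NULL
  scene(px, roles, nodata_value = NULL, georef = georef)
}

#' Write a binary mask
#'
#' Stored as an 8-bit TIFF with values exactly 0 and 1, bit-exact on
#' re-read; the georeference, when given, goes to the JSON sidecar.
#'
#' @param path output path.
#' @param mask matrix with values in \{0, 1\} (logical accepted).
#' @param georef optional opaque georeference copied from the source scene.
#' @return `path`, invisibly.
#' @export
write_mask <- function(path, mask, georef = NULL) {
  mask <- as.matrix(mask) * 1
  if (!all(mask %in% c(0, 1))) stop("write_mask: mask values must be 0/1")
  tiff::writeTIFF(mask, path, bits.per.sample = 8L, compression = "none")
  if (!is.null(georef))
    jsonlite::write_json(list(kind = "mask", georef = georef),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA,
                         null = "null")
  invisible(path)
}

#' Write a single real-valued grid (e.g. a difference image)
#'
#' Same storage scheme as [write_scene()] (32-bit-float TIFF, min-max
#' scaling and georef in the JSON sidecar), for one band.
#'
#' @param path output path.
#' @param g numeric matrix.
#' @param georef optional opaque georeference.
#' @return `path`, invisibly.
#' @export
write_grid <- function(path, g, georef = NULL) {
  g <- as.matrix(g)
  na <- is.na(g)
  lo <- suppressWarnings(min(g, na.rm = TRUE))
  hi <- suppressWarnings(max(g, na.rm = TRUE))
  if (!is.finite(lo)) { lo <- 0; hi <- 1 }
  rng <- hi - lo
  gs <- if (rng > 0) (g - lo) / rng else g * 0
  gs[na] <- 0
  tiff::writeTIFF(gs, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(kind = "grid", band_min = lo, band_max = hi,
                            georef = georef),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path grid path.
#' @return A numeric matrix with attribute `"georef"` when present.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read grid: ", path)
  g <- tiff::readTIFF(path)
  if (file.exists(sidecar_path(path))) {
    aux <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    rng <- aux$band_max - aux$band_min
    g <- if (rng > 0) g * rng + aux$band_min else g + aux$band_min
    attr(g, "georef") <- aux$georef
  }
  g
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path mask path.
#' @return A 0/1 integer matrix, with the georeference (if any) attached as
#'   attribute `"georef"`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  m <- tiff::readTIFF(path)
  out <- (m > 0.5) * 1L
  if (file.exists(sidecar_path(path))) {
    aux <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    attr(out, "georef") <- aux$georef
  }
  out
}
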