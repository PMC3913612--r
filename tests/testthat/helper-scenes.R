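# fixtures built in code: tiny scenes, pseudo bi-temporal pairs, metrics

roles3 <- band_roles("custom", red = 1, nir = 2, mir = 3, cva_bands = 1:3)

# scene from a list of band matrices
scene_from_bands <- function(..., roles = roles3, nodata_value = NULL,
                             georef = NULL) {
  bands <- list(...)
  a <- array(NA_real_, c(dim(bands[[1]]), length(bands)))
  for (b in seq_along(bands)) a[, , b] <- bands[[b]]
  scene(a, roles, nodata_value = nodata_value, georef = georef)
}

# 3-band pseudo-scene whose NIR band carries the signal
nir_scene <- function(nir, fill = 0.5) {
  h <- nrow(nir); w <- ncol(nir)
  scene_from_bands(matrix(fill, h, w), nir, matrix(fill, h, w))
}

jaccard <- function(a, b) sum(a == 1 & b == 1) / sum(a == 1 | b == 1)

mask_kappa <- function(pred, truth)
  kappa_coefficient(confusion_counts(pred, truth))

# orientation used by the pipeline: burn is the bright class of the grid
oriented <- function(mask, g) burnscar:::orient_burn_mask(mask, g)

# exhaustive 2-partition SSE minimizer (oracle for kmeans_split), n <= 15
exhaustive_two_partition <- function(values) {
  n <- length(values)
  best <- Inf
  best_lab <- NULL
  for (code in 1:(2^(n - 1) - 1)) {       # pixel 1 fixed in cluster 1
    lab <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    if (length(unique(lab)) < 2L) next
    sse <- sum((values[lab == 1] - mean(values[lab == 1]))^2) +
           sum((values[lab == 2] - mean(values[lab == 2]))^2)
    if (sse < best - 1e-12) { best <- sse; best_lab <- lab }
  }
  list(sse = best, labels = best_lab)
}

within_sse <- function(values, labels)
  sum(vapply(unique(labels), function(l)
    sum((values[labels == l] - mean(values[labels == l]))^2), 0))

# brute-force Otsu oracle: explicit between-class variance at every bin cut
otsu_bruteforce <- function(g, bins = 256L) {
  v <- as.vector(g); v <- v[!is.na(v)]
  lo <- min(v); hi <- max(v)
  x <- (v - lo) / (hi - lo)
  brk <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(findInterval(x, brk, rightmost.closed = TRUE), bins)
  mids <- (seq_len(bins) - 0.5) / bins
  best <- -Inf; kbest <- NA
  for (k in seq_len(bins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0); n1 <- sum(!in0)
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(mids[bin[in0]]); mu1 <- mean(mids[bin[!in0]])
    bcv <- (n0 / length(x)) * (n1 / length(x)) * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; kbest <- k }
  }
  lo + (kbest / bins) * (hi - lo)
}
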