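# Pixel-spectra preprocessing: vegetation segmentation, spectra extraction,
# band cropping to the analysed 434-953 nm window, Daubechies-9 level-3
# wavelet denoising and 7-point moving-average smoothing, and per-sample
# mean spectra. The fixed pipeline order is
#   calibrate -> segment -> extract -> crop -> wavelet -> moving average ->
#   mean spectrum.

# Daubechies-9 synthesis low-pass filter (orthonormal, 18 taps). Standard
# published coefficients; sum = sqrt(2).
.db9_lo <- c(
  3.93473203162716e-05, -0.0002519631889427101, 0.00023038576352319597,
  0.0018476468830562265, -0.00428150368246343, -0.004723204757751397,
  0.022361662123679096, 0.00025094711483145197, -0.06763282906132997,
  0.03072568147933338, 0.14854074933810638, -0.09684078322297646,
  -0.2932737832791749, 0.13319738582500756, 0.6572880780513005,
  0.6048231236901112, 0.24383467461259034, 0.038077947363878345
)

# cache of per-(n, level) orthonormal approximation bases and per-(n, window)
# combined smoother operators
.leafspec_cache <- new.env(parent = emptyenv())

# level-`level` scaling sequence by the cascade: upsample-and-convolve the
# low-pass filter with itself `level - 1` times
.scaling_sequence <- function(level = 3L) {
  phi <- .db9_lo
  for (i in seq_len(level - 1L)) {
    up <- numeric(2L * length(phi) - 1L)
    up[seq(1L, length(up), by = 2L)] <- phi
    phi <- stats::convolve(up, rev(.db9_lo), type = "open")
  }
  phi
}

# Orthonormal basis (n x m) of the level-3 approximation space on a length-n
# window: the constant vector plus the 2^level-lattice translates of the
# scaling sequence truncated to the window, orthonormalised by SVD with a
# relative cutoff.
.approx_basis <- function(n, level = 3L) {
  key <- sprintf("basis_%d_%d", n, level)
  if (!is.null(.leafspec_cache[[key]])) {
    return(.leafspec_cache[[key]])
  }
  phi <- .scaling_sequence(level)
  L <- length(phi)
  if (n < L) {
    stop(sprintf(
      "input length %d is below the level-%d filter support (%d)", n, level, L
    ), call. = FALSE)
  }
  step <- 2L^level
  k_min <- -((L - 1L) %/% step)
  k_max <- (n - 1L) %/% step
  cols <- list()
  for (k in k_min:k_max) {
    col <- numeric(n)
    idx <- seq_len(L) + k * step
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) next
    col[idx[ok]] <- phi[ok]
    if (sqrt(sum(col^2)) > 1e-8) cols[[length(cols) + 1L]] <- col
  }
  S <- do.call(cbind, cols)
  # constants belong to the ideal approximation space (the scaling functions
  # form a partition of unity); carry them as an exact basis vector and
  # orthogonalise the truncated translates against them
  c0 <- rep(1 / sqrt(n), n)
  S <- S - c0 %o% as.numeric(crossprod(c0, S))
  sv <- svd(S)
  keep <- sv$d > 1e-7 * sv$d[1L]
  Q <- cbind(c0, sv$u[, keep, drop = FALSE], deparse.level = 0)
  .leafspec_cache[[key]] <- Q
  Q
}

#' Wavelet denoising of a reflectance spectrum
#'
#' Removes fine-scale noise by a 3-level Daubechies-9 wavelet approximation:
#' the spectrum is orthogonally projected onto the space spanned by the
#' level-3 scaling functions on the band window (all detail coefficients
#' zero). Being an orthogonal projection, the operation is exactly
#' idempotent and preserves constants; boundary handling is by restriction
#' of the translation lattice to the window, which avoids edge artifacts at
#' the first and last retained bands.
#'
#' @param spectrum numeric vector (or a pixels-by-bands matrix, denoised
#'   row-wise).
#' @param level decomposition level (default 3).
#' @return Denoised spectrum (or matrix), same dimensions as the input.
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 256)) + rnorm(256, 0, 0.1)
#' plot(x, type = "l"); lines(wavelet_denoise(x), lwd = 2)
#' @export
wavelet_denoise <- function(spectrum, level = 3L) {
  if (is.matrix(spectrum)) {
    Q <- .approx_basis(ncol(spectrum), level)
    return(spectrum %*% Q %*% t(Q))
  }
  x <- as.numeric(spectrum)
  Q <- .approx_basis(length(x), level)
  as.numeric(Q %*% crossprod(Q, x))
}

#' Moving-average smoothing
#'
#' Centred moving average with an odd window; near the edges the window
#' shrinks symmetrically so the smoothed value is always a mean of observed
#' points centred on the target band.
#'
#' @param spectrum numeric vector (or pixels-by-bands matrix, smoothed
#'   row-wise).
#' @param window odd window length (default 7).
#' @return Smoothed values, same dimensions as the input.
#' @export
moving_average <- function(spectrum, window = 7L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (is.matrix(spectrum)) {
    return(spectrum %*% t(.ma_operator(ncol(spectrum), window)))
  }
  x <- as.numeric(spectrum)
  as.numeric(.ma_operator(length(x), window) %*% x)
}

# moving-average as an explicit n x n linear operator (rows = output bands)
.ma_operator <- function(n, window) {
  h <- window %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    M[i, (i - k):(i + k)] <- 1 / (2L * k + 1L)
  }
  M
}

# combined denoise-then-smooth operator, cached by (n, level, window);
# applied to pixel matrices as X %*% t(A)
.smoother_operator <- function(n, level = 3L, window = 7L) {
  key <- sprintf("smooth_%d_%d_%d", n, level, window)
  if (!is.null(.leafspec_cache[[key]])) {
    return(.leafspec_cache[[key]])
  }
  Q <- .approx_basis(n, level)
  A <- .ma_operator(n, window) %*% Q %*% t(Q)
  .leafspec_cache[[key]] <- A
  A
}

#' Segment vegetation pixels
#'
#' Thresholds the normalised difference vegetation index computed from the
#' bands nearest 800 and 680 nm, `NDVI = (R800 - R680) / (R800 + R680)`,
#' then removes connected components (4-connectivity) smaller than
#' `min_component` pixels.
#'
#' @param cube a reflectance [hyper_cube()] whose wavelength axis covers
#'   680 and 800 nm.
#' @param threshold NDVI threshold (default 0.4).
#' @param min_component minimum connected-component size in pixels.
#' @return Logical mask, `rows x cols`.
#' @export
segment_plant <- function(cube, threshold = 0.4, min_component = 20L) {
  if (!inherits(cube, "hyper_cube")) stop("`cube` must be a hyper_cube", call. = FALSE)
  if (cube$kind != "reflectance") {
    stop("segmentation requires a reflectance cube (calibrate first)", call. = FALSE)
  }
  wl <- cube$wavelengths
  if (min(wl) > 680 || max(wl) < 800) {
    stop("wavelength axis must cover 680-800 nm for NDVI segmentation", call. = FALSE)
  }
  b680 <- which.min(abs(wl - 680))
  b800 <- which.min(abs(wl - 800))
  r680 <- cube$data[, , b680, drop = TRUE]
  r800 <- cube$data[, , b800, drop = TRUE]
  ndvi <- (r800 - r680) / pmax(r800 + r680, .Machine$double.eps)
  mask <- ndvi > threshold
  if (any(mask)) {
    labels <- label_components(mask)
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= min_component)
    mask <- matrix(labels %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) {
    stop(sprintf(
      "segmentation produced an empty mask (NDVI threshold %.2f)", threshold
    ), call. = FALSE)
  }
  mask
}

#' Extract per-pixel spectra from masked pixels
#'
#' One row per `TRUE` mask pixel, in row-major scan order (all columns of
#' row 1, then row 2, ...), with the originating coordinates recorded.
#'
#' @param cube a [hyper_cube()].
#' @param mask logical matrix matching the cube's spatial dimensions.
#' @param sample_id optional identifier carried along.
#' @param label optional treatment label carried along.
#' @return An object of class `pixel_spectra`: `spectra` (pixels x bands),
#'   `wavelengths`, `coords` (two-column matrix of row/col), `sample_id`,
#'   `label`.
#' @export
extract_pixel_spectra <- function(cube, mask, sample_id = NULL, label = NULL) {
  if (!inherits(cube, "hyper_cube")) stop("`cube` must be a hyper_cube", call. = FALSE)
  d <- dim(cube$data)
  if (!is.matrix(mask) || !all(dim(mask) == d[1:2])) {
    stop(sprintf(
      "mask dimensions (%s) do not match cube spatial dimensions (%d x %d)",
      paste(dim(mask), collapse = "x"), d[1L], d[2L]
    ), call. = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask selects no pixels", call. = FALSE)
  ord <- order(idx[, 1L], idx[, 2L]) # row-major scan order
  idx <- idx[ord, , drop = FALSE]
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  spectra <- flat[idx[, 1L] + (idx[, 2L] - 1L) * d[1L], , drop = FALSE]
  structure(list(
    spectra = spectra,
    wavelengths = cube$wavelengths,
    coords = unname(idx),
    sample_id = sample_id,
    label = label
  ), class = "pixel_spectra")
}

#' @export
print.pixel_spectra <- function(x, ...) {
  cat(sprintf(
    "<pixel_spectra> %d pixels x %d bands (%.1f-%.1f nm)%s\n",
    nrow(x$spectra), ncol(x$spectra),
    min(x$wavelengths), max(x$wavelengths),
    if (!is.null(x$sample_id)) paste0(", sample ", x$sample_id) else ""
  ))
  invisible(x)
}

#' Crop spectra to a wavelength window
#'
#' Keeps the contiguous band run that covers `[lo_nm, hi_nm]`: from the last
#' band at or below `lo_nm` through the first band at or above `hi_nm`.
#' With the default 512-band 380-1030 nm axis and the default 434-953 nm
#' window this retains exactly 410 bands. When `lo_nm`/`hi_nm` coincide with
#' band centres this is the plain inclusive-range crop.
#'
#' @param px a `pixel_spectra` object.
#' @param lo_nm,hi_nm window limits in nm (defaults 434 and 953).
#' @return A `pixel_spectra` restricted to the retained bands.
#' @export
crop_bands <- function(px, lo_nm = 434, hi_nm = 953) {
  if (!inherits(px, "pixel_spectra")) stop("`px` must be pixel_spectra", call. = FALSE)
  if (lo_nm > hi_nm) stop("`lo_nm` must not exceed `hi_nm`", call. = FALSE)
  keep <- .crop_indices(px$wavelengths, lo_nm, hi_nm)
  px$spectra <- px$spectra[, keep, drop = FALSE]
  px$wavelengths <- px$wavelengths[keep]
  px
}

.crop_indices <- function(wl, lo_nm, hi_nm) {
  if (max(wl) < lo_nm || min(wl) > hi_nm) {
    stop(sprintf(
      "window [%g, %g] nm lies outside the wavelength axis [%g, %g] nm",
      lo_nm, hi_nm, min(wl), max(wl)
    ), call. = FALSE)
  }
  at_or_below <- which(wl <= lo_nm)
  first <- if (length(at_or_below)) max(at_or_below) else 1L
  at_or_above <- which(wl >= hi_nm)
  last <- if (length(at_or_above)) min(at_or_above) else length(wl)
  first:last
}

#' Band-wise mean spectrum of a pixel set
#'
#' @param px a `pixel_spectra` object with at least one pixel.
#' @return Numeric vector, one value per band.
#' @export
mean_spectrum <- function(px) {
  if (!inherits(px, "pixel_spectra")) stop("`px` must be pixel_spectra", call. = FALSE)
  if (nrow(px$spectra) < 1L) stop("no pixels to average", call. = FALSE)
  colMeans(px$spectra)
}

#' Denoise and smooth all pixel spectra of a sample
#'
#' Applies [wavelet_denoise()] followed by [moving_average()] to every row,
#' using one precomputed linear operator for speed.
#'
#' @param px a `pixel_spectra` object.
#' @param window moving-average window (odd, default 7).
#' @param level wavelet decomposition level (default 3).
#' @return The `pixel_spectra` with smoothed rows.
#' @export
preprocess_pixels <- function(px, window = 7L, level = 3L) {
  if (!inherits(px, "pixel_spectra")) stop("`px` must be pixel_spectra", call. = FALSE)
  A <- .smoother_operator(ncol(px$spectra), level, window)
  px$spectra <- px$spectra %*% t(A)
  px
}
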