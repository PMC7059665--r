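#' Principal component analysis of spectra
#'
#' Mean-centred PCA (no variance scaling: reflectance bands share units) via
#' singular value decomposition. Component signs are fixed so that each
#' loading's largest-magnitude element is positive, making score images
#' reproducible across runs and platforms.
#'
#' @param X samples-by-bands numeric matrix (>= 2 rows).
#' @param k number of components to retain (default 10, capped at
#'   `min(n - 1, bands)`).
#' @return An object of class `spec_pca`: `mean` (band-wise mean),
#'   `loadings` (bands x k, orthonormal columns ordered by explained
#'   variance), `explained` (per-retained-component fractions of total
#'   variance, non-increasing), `k`.
#' @examples
#' X <- matrix(rnorm(50), 10, 5)
#' p <- fit_pca(X, k = 2)
#' round(crossprod(p$loadings), 10) # identity
#' @export
fit_pca <- function(X, k = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  k <- as.integer(k)
  kmax <- min(n - 1L, p)
  if (k < 1L || k > kmax) {
    stop(sprintf("`k` must be between 1 and min(n - 1, bands) = %d", kmax),
      call. = FALSE
    )
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  total_var <- sum(Xc^2)
  if (total_var < .Machine$double.eps) {
    stop("input has zero variance; PCA is degenerate", call. = FALSE)
  }
  sv <- svd(Xc, nu = 0, nv = kmax)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| element of each loading is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(list(
    mean = mu,
    loadings = loadings,
    explained = (sv$d[seq_len(k)]^2) / sum(sv$d^2),
    k = k
  ), class = "spec_pca")
}

#' @export
print.spec_pca <- function(x, ...) {
  cat(sprintf(
    "<spec_pca> %d components over %d bands; explained: %s\n",
    x$k, length(x$mean),
    paste(sprintf("%.1f%%", 100 * x$explained[seq_len(min(3L, x$k))]),
      collapse = ", "
    )
  ))
  cat(sprintf(
    "  cumulative over %d PCs: %.2f%%\n", x$k, 100 * sum(x$explained)
  ))
  invisible(x)
}

#' Project spectra onto fitted principal components
#'
#' Computes scores `(X - mean) %*% loadings`.
#'
#' @param model a [fit_pca()] model.
#' @param X samples-by-bands matrix with the model's band count.
#' @return Scores matrix, `n x k`.
#' @export
transform_pca <- function(model, X) {
  if (!inherits(model, "spec_pca")) stop("`model` must be a spec_pca", call. = FALSE)
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(model$mean)) {
    stop(sprintf(
      "band count (%d) does not match the PCA model (%d)",
      ncol(X), length(model$mean)
    ), call. = FALSE)
  }
  sweep(X, 2L, model$mean, "-") %*% model$loadings
}

#' @export
predict.spec_pca <- function(object, newdata, ...) {
  transform_pca(object, newdata)
}

#' Principal component score image
#'
#' Projects the pixel spectra on one component and writes each pixel's score
#' back to its image coordinate; background pixels are `NA`.
#'
#' @param px a `pixel_spectra` object (band count matching the model).
#' @param model a [fit_pca()] model.
#' @param pc_index 1-based component index (<= `model$k`).
#' @param shape integer vector `c(rows, cols)` of the target image.
#' @return Numeric `rows x cols` matrix of scores with `NA` background.
#' @export
score_image <- function(px, model, pc_index, shape) {
  if (!inherits(px, "pixel_spectra")) stop("`px` must be pixel_spectra", call. = FALSE)
  if (!inherits(model, "spec_pca")) stop("`model` must be a spec_pca", call. = FALSE)
  pc_index <- as.integer(pc_index)
  if (pc_index < 1L || pc_index > model$k) {
    stop(sprintf("`pc_index` must be in 1..%d", model$k), call. = FALSE)
  }
  shape <- as.integer(shape)
  if (any(px$coords[, 1L] > shape[1L]) || any(px$coords[, 2L] > shape[2L])) {
    stop("pixel coordinates fall outside `shape`", call. = FALSE)
  }
  scores <- transform_pca(model, px$spectra)[, pc_index]
  img <- matrix(NA_real_, shape[1L], shape[2L])
  img[px$coords] <- scores
  img
}

#' Serialise a PCA model to a flat text file
#' @param model a `spec_pca` model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pca <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("k: %d", model$k), con)
  writeLines(sprintf("bands: %d", length(model$mean)), con)
  writeLines(paste("mean:", paste(format(model$mean, digits = 17), collapse = " ")), con)
  writeLines(paste("explained:", paste(format(model$explained, digits = 17), collapse = " ")), con)
  for (j in seq_len(model$k)) {
    writeLines(paste0("loading_", j, ": ",
      paste(format(model$loadings[, j], digits = 17), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PCA model written by [write_pca()]
#' @param path input path.
#' @return A `spec_pca` model.
#' @export
read_pca <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)[1L]
    trimws(sub("^[^:]*:", "", ln))
  }
  k <- as.integer(val("k"))
  mean <- as.numeric(strsplit(val("mean"), " +")[[1L]])
  explained <- as.numeric(strsplit(val("explained"), " +")[[1L]])
  loadings <- sapply(seq_len(k), function(j) {
    as.numeric(strsplit(val(paste0("loading_", j)), " +")[[1L]])
  })
  structure(list(
    mean = mean, loadings = loadings, explained = explained, k = k
  ), class = "spec_pca")
}
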