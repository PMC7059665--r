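# Model evaluation: confusion matrices, total classification accuracy,
# Cohen's kappa, pixel-wise prediction maps and their treatment-level
# summaries.

#' Confusion matrix of actual vs predicted treatment labels
#'
#' @param actual,predicted equal-length label vectors with values in
#'   `labels`.
#' @param labels the label set (default `1:3` = CK, Q, S).
#' @return Integer matrix of class `confusion_matrix`, rows = actual,
#'   columns = predicted.
#' @examples
#' confusion_matrix(c(1, 2, 3), c(1, 2, 3))
#' @export
confusion_matrix <- function(actual, predicted, labels = 1:3) {
  if (length(actual) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  if (!all(actual %in% labels) || !all(predicted %in% labels)) {
    stop("labels outside the declared label set", call. = FALSE)
  }
  f <- function(v) factor(v, levels = labels)
  cm <- table(actual = f(actual), predicted = f(predicted))
  cm <- matrix(as.integer(cm), length(labels), length(labels),
    dimnames = list(
      actual = treatment_levels()[seq_along(labels)],
      predicted = treatment_levels()[seq_along(labels)]
    )
  )
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

.as_cm <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("`cm` must be a square confusion matrix", call. = FALSE)
  }
  if (any(cm < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  cm
}

#' Total classification accuracy
#'
#' Fraction of correctly classified samples: `trace(cm) / sum(cm)`.
#'
#' @param cm a square confusion matrix (rows actual, columns predicted).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  cm <- .as_cm(cm)
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = trace(cm) / n` and `p_e = sum_i row_i * col_i / n^2` (unweighted).
#'
#' @param cm a square confusion matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- .as_cm(cm)
  n <- sum(cm)
  if (n == 0) stop("confusion matrix is empty", call. = FALSE)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (p_e >= 1) {
    stop("kappa is undefined: expected agreement is 1 (all mass in one cell)",
      call. = FALSE
    )
  }
  (p_o - p_e) / (1 - p_e)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted)\n")
  print(unclass(x))
  cat(sprintf(
    "accuracy %.2f%%, kappa %.2f%%\n",
    100 * accuracy(x), 100 * cohen_kappa(x)
  ))
  invisible(x)
}

#' Pixel-wise prediction map
#'
#' Classifies every plant pixel of a reflectance cube with the trained
#' model: the pixel spectrum is cropped to the analysed window, wavelet
#' denoised, moving-average smoothed, projected onto the PCA features and
#' classified. Background pixels are `NA`.
#'
#' @param cube a reflectance [hyper_cube()].
#' @param mask logical plant mask (e.g. from [segment_plant()]).
#' @param pca a [fit_pca()] model fitted on preprocessed sample spectra.
#' @param model an [rbf_svc()] classifier trained on the PCA scores.
#' @param lo_nm,hi_nm crop window (defaults 434 and 953 nm).
#' @param window,level smoothing parameters (defaults 7 and 3).
#' @return Object of class `prediction_map`: `labels` (rows x cols integer
#'   matrix, `NA` background), `fractions` (named per-category pixel
#'   fractions over plant pixels, summing to 1), `n_pixels`.
#' @export
prediction_map <- function(cube, mask, pca, model,
                           lo_nm = 434, hi_nm = 953,
                           window = 7L, level = 3L) {
  if (!inherits(model, "rbf_svc")) {
    stop("`model` must be a trained rbf_svc classifier", call. = FALSE)
  }
  if (!inherits(pca, "spec_pca")) stop("`pca` must be a spec_pca", call. = FALSE)
  px <- extract_pixel_spectra(cube, mask)
  px <- crop_bands(px, lo_nm, hi_nm)
  px <- preprocess_pixels(px, window = window, level = level)
  scores <- transform_pca(pca, px$spectra)
  pred <- predict(model, scores)
  img <- matrix(NA_integer_, dim(cube$data)[1L], dim(cube$data)[2L])
  img[px$coords] <- pred
  lv <- treatment_levels()[model$classes]
  fractions <- as.numeric(table(factor(pred, levels = model$classes))) / length(pred)
  names(fractions) <- lv
  structure(list(
    labels = img,
    fractions = fractions,
    n_pixels = length(pred)
  ), class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf(
    "<prediction_map> %d plant pixels; fractions: %s\n",
    x$n_pixels,
    paste(sprintf("%s %.1f%%", names(x$fractions), 100 * x$fractions),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Treatment-level summary of prediction maps
#'
#' Mean and standard deviation of the per-category pixel fractions of the
#' maps in each true-treatment group.
#'
#' @param maps list of [prediction_map()] objects.
#' @param groups true treatment label per map.
#' @return data.frame with one row per (group, predicted category):
#'   `treatment`, `predicted`, `mean_fraction`, `sd_fraction`, `n_maps`.
#' @export
pixel_summary <- function(maps, groups) {
  if (length(maps) == 0L) stop("no maps supplied", call. = FALSE)
  if (length(maps) != length(groups)) {
    stop("`groups` must have one label per map", call. = FALSE)
  }
  groups <- as.integer(groups)
  cats <- names(maps[[1L]]$fractions)
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    sel <- which(groups == g)
    if (length(sel) == 0L) stop(sprintf("group %d is empty", g), call. = FALSE)
    fr <- do.call(rbind, lapply(maps[sel], function(m) m$fractions))
    data.frame(
      treatment = treatment_levels()[g],
      predicted = cats,
      mean_fraction = colMeans(fr),
      sd_fraction = if (length(sel) > 1L) apply(fr, 2L, stats::sd) else 0,
      n_maps = length(sel),
      row.names = NULL
    )
  }))
  out
}

#' Metrics report for a set of splits
#'
#' @param sets named list, each element a list with elements `actual` and
#'   `predicted`.
#' @return data.frame with one row per set: accuracy, kappa, and the nine
#'   confusion counts in row-major order.
#' @export
metrics_report <- function(sets) {
  do.call(rbind, lapply(names(sets), function(nm) {
    cm <- confusion_matrix(sets[[nm]]$actual, sets[[nm]]$predicted)
    counts <- as.integer(t(unclass(cm)))
    df <- data.frame(
      set = nm,
      accuracy = accuracy(cm),
      kappa = cohen_kappa(cm)
    )
    cn <- outer(rownames(cm), colnames(cm), function(a, b) paste0(a, "_", b))
    df[as.vector(t(cn))] <- as.list(counts)
    df
  }))
}
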