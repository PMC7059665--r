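# Deterministic dataset splitting: Kennard-Stone sample selection and the
# per-class 4:1:1 train/validation/test split.

# Kennard-Stone ranking of all samples: the first two are the maximally
# distant pair (lower index first), then each next sample maximises its
# minimum Euclidean distance to the already-selected set; ties broken by
# lowest index.
.ks_rank <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("Kennard-Stone needs at least 2 samples", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  if (max(D) <= 0) {
    stop("all samples coincide; Kennard-Stone is degenerate", call. = FALSE)
  }
  # maximal pair, lowest indices on ties
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[flat[, 1L] < flat[, 2L], , drop = FALSE]
  flat <- flat[order(flat[, 1L], flat[, 2L]), , drop = FALSE]
  sel <- c(flat[1L, 1L], flat[1L, 2L])
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  while (length(sel) < n) {
    mind[sel] <- -Inf
    nxt <- which.max(mind) # which.max returns the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  unname(as.integer(sel))
}

#' Kennard-Stone calibration/prediction split
#'
#' Deterministically selects a representative calibration subset: the seed
#' pair is the two samples at maximal Euclidean distance, then samples are
#' added one at a time maximising the minimum distance to the selected set,
#' until `ceiling(calibration_fraction * n)` samples are chosen. Ties are
#' broken by lowest row index, so the result depends only on the data.
#'
#' @param X samples-by-features numeric matrix.
#' @param calibration_fraction fraction assigned to the calibration set
#'   (default 2/3).
#' @return List with integer index vectors `calibration` and `prediction`.
#' @examples
#' X <- matrix(c(0, 1, 10), ncol = 1)
#' kennard_stone_split(X)$calibration # rows 1 and 3
#' @export
kennard_stone_split <- function(X, calibration_fraction = 2 / 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (calibration_fraction <= 0 || calibration_fraction > 1) {
    stop("`calibration_fraction` must be in (0, 1]", call. = FALSE)
  }
  n_cal <- min(n, max(2L, ceiling(calibration_fraction * n)))
  ranks <- .ks_rank(X)
  cal <- sort(ranks[seq_len(n_cal)])
  list(calibration = cal, prediction = setdiff(seq_len(n), cal))
}

#' Per-class 4:1:1 train/validation/test split
#'
#' Within each class, samples are ranked by the Kennard-Stone procedure and
#' the ranks are dealt round-robin into train/validation/test with the
#' repeating pattern train, train, train, train, validation, test. The
#' split is deterministic given the data, covers every sample exactly once,
#' and keeps each class's validation and test counts within one of
#' `floor(n_class / 6)`.
#'
#' @param labels treatment labels (values in 1..3), one per row of `X`.
#' @param X samples-by-features matrix used for the Kennard-Stone ranking.
#' @return An object of class `dataset_split` with integer index vectors
#'   `train`, `validation` and `test`.
#' @export
split_4_1_1 <- function(labels, X) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) {
    stop("`labels` length must match rows of `X`", call. = FALSE)
  }
  pattern <- c("train", "train", "train", "train", "validation", "test")
  out <- list(train = integer(), validation = integer(), test = integer())
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 6L) {
      stop(sprintf(
        "class %d has only %d samples; at least 6 are needed for a 4:1:1 split",
        cl, length(idx)
      ), call. = FALSE)
    }
    ranks <- .ks_rank(X[idx, , drop = FALSE])
    dealt <- pattern[(seq_along(ranks) - 1L) %% 6L + 1L]
    for (set in names(out)) {
      out[[set]] <- c(out[[set]], idx[ranks[dealt == set]])
    }
  }
  out <- lapply(out, sort)
  class(out) <- "dataset_split"
  out
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> train %d / validation %d / test %d\n",
    length(x$train), length(x$validation), length(x$test)
  ))
  invisible(x)
}

#' Export a split as a CSV of sample id to subset
#' @param split a `dataset_split`.
#' @param ids sample identifiers, one per sample.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, ids, path) {
  n <- length(split$train) + length(split$validation) + length(split$test)
  subset <- character(n)
  subset[split$train] <- "train"
  subset[split$validation] <- "validation"
  subset[split$test] <- "test"
  utils::write.csv(
    data.frame(sample_id = ids, subset = subset),
    path,
    row.names = FALSE
  )
  invisible(path)
}
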