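# Published benchmark confusion tables for the two rice cultivars
# (XS 134, ZJ 88) under full-spectrum and ten-PC-score SVC models.

#' Load the shipped benchmark confusion tables
#'
#' Twelve 3x3 confusion matrices (two cultivars x two feature modes x
#' train/validation/test) distributed with the package as a plain-text
#' table, together with the originally printed accuracy and kappa
#' percentages.
#'
#' @param path optional path to a CSV with the same layout (defaults to the
#'   shipped file).
#' @return data.frame with columns `cultivar`, `features`, `set`, the nine
#'   confusion counts `CK_CK` ... `S_S` (actual_predicted), and
#'   `printed_accuracy`, `printed_kappa` (percent).
#' @seealso [benchmark_metrics()]
#' @export
benchmark_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "svc_confusion_tables.csv",
      package = "leafspec"
    )
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute accuracy and kappa from the benchmark confusion tables
#'
#' Rebuilds each stored confusion matrix and recomputes total accuracy and
#' unweighted Cohen's kappa from the counts.
#'
#' @param tables a data.frame as returned by [benchmark_tables()].
#' @return The input with `accuracy` and `kappa` columns appended (percent,
#'   computed from the counts).
#' @examples
#' m <- benchmark_metrics()
#' m[m$cultivar == "ZJ88", c("set", "features", "accuracy", "kappa")]
#' @export
benchmark_metrics <- function(tables = benchmark_tables()) {
  count_cols <- as.vector(outer(c("CK", "Q", "S"), c("CK", "Q", "S"),
    function(a, b) paste0(a, "_", b)
  ))
  # columns are actual_predicted; fill row-wise (actual in rows)
  tables$accuracy <- NA_real_
  tables$kappa <- NA_real_
  for (i in seq_len(nrow(tables))) {
    cm <- matrix(as.numeric(tables[i, count_cols]), 3L, 3L)
    # outer() above varies `actual` fastest, so cm is already actual x predicted
    tables$accuracy[i] <- 100 * accuracy(cm)
    tables$kappa[i] <- 100 * cohen_kappa(cm)
  }
  tables
}
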