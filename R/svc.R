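# Soft-margin support vector classification with a radial basis function
# kernel, trained from scratch by sequential minimal optimisation on the
# dual problem
#   min 1/2 a' Q a - e' a,  Q_ij = y_i y_j K(x_i, x_j),
#   subject to y' a = 0 and 0 <= a_i <= C,
# with K(u, v) = exp(-gamma * ||u - v||^2) and decision function
#   f(x) = sum_i a_i y_i K(x_i, x) + b.
# Multiclass problems use a one-vs-one ensemble with majority voting.

#' Radial basis function kernel
#'
#' `K(u, v) = exp(-gamma * ||u - v||^2)`, in (0, 1].
#'
#' @param u,v numeric vectors of equal length, or matrices with samples in
#'   rows (the full cross-kernel matrix is returned).
#' @param gamma positive kernel width parameter.
#' @return Scalar for vector inputs; `nrow(u) x nrow(v)` matrix otherwise.
#' @examples
#' rbf_kernel(0, 1, gamma = 1) # exp(-1)
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("`gamma` must be a positive scalar", call. = FALSE)
  }
  if (is.matrix(u) || is.matrix(v)) {
    u <- if (is.matrix(u)) u else matrix(u, nrow = 1L)
    v <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
    if (ncol(u) != ncol(v)) stop("dimension mismatch", call. = FALSE)
    return(exp(-gamma * .sqdist(u, v)))
  }
  if (length(u) != length(v)) stop("`u` and `v` must have equal length", call. = FALSE)
  exp(-gamma * sum((u - v)^2))
}

# squared Euclidean cross-distances, rows of A vs rows of B
.sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Fit a binary soft-margin RBF support vector machine
#'
#' Solves the dual quadratic program by sequential minimal optimisation
#' (maximal-violating-pair working sets) to KKT gap `tol`. The bias is the
#' mean over free support vectors (`0 < alpha < C`) of
#' `y_i - sum_j alpha_j y_j K(x_j, x_i)`; when no support vector is free it
#' is the midpoint of the interval allowed by the bound vectors.
#'
#' @param x training inputs, samples in rows.
#' @param y labels in `{-1, +1}` (both classes present).
#' @param C positive cost parameter.
#' @param gamma positive RBF width.
#' @param tol KKT tolerance (default 1e-3).
#' @param max_iter iteration cap (default `1e4 * n`).
#' @return An object of class `svc_binary`: `support_vectors`, `dual_coef`
#'   (`alpha_i * y_i` per support vector), `bias`, `gamma`, `cost`,
#'   `objective` (dual objective value), `kkt_gap`, `iterations`,
#'   `class_pair` (labels mapped to +1 / -1, when fitted via [rbf_svc()]).
#' @examples
#' m <- svc_binary(matrix(c(0, 1)), c(-1, 1), C = 1e6, gamma = 1)
#' m$dual_coef # +/- 1 / (1 - exp(-1))
#' @export
svc_binary <- function(x, y, C, gamma, tol = 1e-3, max_iter = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("`y` length must match rows of `x`", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("`y` must be coded -1 / +1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in `y`", call. = FALSE)
  }
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  n <- nrow(x)
  if (is.null(max_iter)) max_iter <- 1e4 * n
  K <- rbf_kernel(x, x, gamma)
  sol <- .smo_solve(K, y, C, tol, as.integer(max_iter))
  if (!sol$converged) {
    stop(sprintf(
      "SMO did not converge in %d iterations (KKT gap %.3g > tol %.3g)",
      sol$iterations, sol$kkt_gap, tol
    ), call. = FALSE)
  }
  sv <- which(sol$alpha > 1e-10)
  structure(list(
    support_vectors = x[sv, , drop = FALSE],
    dual_coef = sol$alpha[sv] * y[sv],
    alpha = sol$alpha[sv],
    bias = sol$b,
    gamma = gamma,
    cost = C,
    objective = sol$objective,
    kkt_gap = sol$kkt_gap,
    sum_alpha_y = sol$sum_alpha_y,
    iterations = sol$iterations,
    n_train = n,
    class_pair = NULL
  ), class = "svc_binary")
}

#' Pre-sign decision values of a binary machine
#'
#' `f(x) = sum_i dual_coef_i K(sv_i, x) + b`; the class is `sign(f)`.
#'
#' @param model an [svc_binary()] model.
#' @param x inputs, samples in rows (or a single vector).
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, x) {
  if (!inherits(model, "svc_binary")) stop("`model` must be svc_binary", call. = FALSE)
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != ncol(model$support_vectors)) {
    stop(sprintf(
      "input dimension (%d) does not match training dimension (%d)",
      ncol(x), ncol(model$support_vectors)
    ), call. = FALSE)
  }
  Kx <- rbf_kernel(x, model$support_vectors, model$gamma)
  as.numeric(Kx %*% model$dual_coef + model$bias)
}

#' @export
print.svc_binary <- function(x, ...) {
  cat(sprintf(
    "<svc_binary> C = %.3g, gamma = %.3g, %d support vectors, bias %.4g\n",
    x$cost, x$gamma, nrow(x$support_vectors), x$bias
  ))
  invisible(x)
}

#' Fit a one-vs-one multiclass RBF support vector classifier
#'
#' Trains one binary soft-margin machine per unordered label pair (on that
#' pair's samples only; the first label of the pair is coded +1) and
#' predicts by majority vote.
#'
#' @param x training inputs, samples in rows.
#' @param labels class labels (integers; three treatment groups in the
#'   intended use, but any number of classes >= 2 works).
#' @param C,gamma shared cost and kernel width for all machines.
#' @param tol,max_iter passed to [svc_binary()].
#' @return An object of class `rbf_svc` with elements `machines` (one
#'   `svc_binary` per pair), `classes`, `C`, `gamma`.
#' @seealso [predict.rbf_svc()], [svc_grid_search()]
#' @export
rbf_svc <- function(x, labels, C = 1, gamma = 1, tol = 1e-3, max_iter = NULL) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) {
    stop("`labels` length must match rows of `x`", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 1L)) stop("every class needs at least one sample", call. = FALSE)
  pairs <- utils::combn(classes, 2L)
  machines <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]
    b <- pairs[2L, p]
    sel <- labels %in% c(a, b)
    m <- svc_binary(
      x[sel, , drop = FALSE],
      ifelse(labels[sel] == a, 1, -1),
      C = C, gamma = gamma, tol = tol, max_iter = max_iter
    )
    m$class_pair <- c(positive = a, negative = b)
    machines[[p]] <- m
  }
  structure(list(
    machines = machines,
    classes = classes,
    C = C,
    gamma = gamma,
    dim = ncol(x)
  ), class = "rbf_svc")
}

#' Predict treatment labels with a fitted classifier
#'
#' Majority vote over the pairwise machines. Vote ties are broken by the
#' largest sum of absolute decision values among the tied labels, then by
#' the smallest label value.
#'
#' @param object an [rbf_svc()] model.
#' @param newdata inputs, samples in rows.
#' @param ... unused.
#' @return Integer vector of predicted labels.
#' @export
predict.rbf_svc <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(x) != object$dim) {
    stop(sprintf(
      "input dimension (%d) does not match training dimension (%d)",
      ncol(x), object$dim
    ), call. = FALSE)
  }
  n <- nrow(x)
  k <- length(object$classes)
  votes <- matrix(0L, n, k, dimnames = list(NULL, object$classes))
  strength <- matrix(0, n, k, dimnames = list(NULL, object$classes))
  for (m in object$machines) {
    f <- decision_values(m, x)
    pos <- as.character(m$class_pair[["positive"]])
    neg <- as.character(m$class_pair[["negative"]])
    winner <- ifelse(f >= 0, pos, neg)
    for (cl in c(pos, neg)) {
      w <- winner == cl
      votes[w, cl] <- votes[w, cl] + 1L
      strength[, cl] <- strength[, cl] + abs(f)
    }
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1L) {
      s <- strength[i, best]
      best <- best[s == max(s)]
    }
    out[i] <- object$classes[min(best)]
  }
  out
}

#' @export
print.rbf_svc <- function(x, ...) {
  cat(sprintf(
    "<rbf_svc> %d classes, %d pairwise machines, C = %.3g, gamma = %.3g\n",
    length(x$classes), length(x$machines), x$C, x$gamma
  ))
  invisible(x)
}

#' @export
summary.rbf_svc <- function(object, ...) {
  cat(sprintf(
    "One-vs-one RBF support vector classifier (%d classes)\n",
    length(object$classes)
  ))
  cat(sprintf("  C = %.4g, gamma = %.4g, input dimension %d\n",
    object$C, object$gamma, object$dim))
  for (m in object$machines) {
    cat(sprintf(
      "  pair %d vs %d: %d support vectors, bias %.4g, dual objective %.6g\n",
      m$class_pair[["positive"]], m$class_pair[["negative"]],
      nrow(m$support_vectors), m$bias, m$objective
    ))
  }
  invisible(object)
}

#' Decade grid for the SVC grid search
#'
#' @param n_lo,n_hi decade exponent range (defaults -8 and 8, giving the
#'   17 x 17 grid of `10^N` values).
#' @return data.frame with columns `C` and `gamma`, one row per cell.
#' @export
svc_grid <- function(n_lo = -8L, n_hi = 8L) {
  v <- 10^(seq.int(n_lo, n_hi))
  expand.grid(C = v, gamma = v, KEEP.OUT.ATTRS = FALSE)
}

#' Grid search over cost and kernel width
#'
#' Trains one one-vs-one classifier per `(C, gamma)` cell on the training
#' set and records training and validation accuracy. The chosen cell
#' maximises validation accuracy; ties are broken by higher training
#' accuracy, then smaller `C`, then smaller `gamma`.
#'
#' @param x_train,labels_train training samples and labels.
#' @param x_val,labels_val validation samples and labels.
#' @param grid data.frame of `C`, `gamma` cells (default [svc_grid()]).
#' @param tol,max_iter passed to the solver.
#' @return An object of class `svc_grid_search`: `results` (the grid with
#'   `train_accuracy`, `val_accuracy`), `best` (chosen row), `model` (the
#'   classifier refitted at the chosen cell).
#' @export
svc_grid_search <- function(x_train, labels_train, x_val, labels_val,
                            grid = svc_grid(), tol = 1e-3, max_iter = NULL) {
  if (nrow(grid) < 1L) stop("`grid` must contain at least one cell", call. = FALSE)
  x_train <- as.matrix(x_train)
  x_val <- as.matrix(x_val)
  res <- grid
  res$train_accuracy <- NA_real_
  res$val_accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    model <- tryCatch(
      rbf_svc(x_train, labels_train,
        C = grid$C[i], gamma = grid$gamma[i],
        tol = tol, max_iter = max_iter
      ),
      error = function(e) {
        stop(sprintf(
          "grid cell (C = %.3g, gamma = %.3g): %s",
          grid$C[i], grid$gamma[i], conditionMessage(e)
        ), call. = FALSE)
      }
    )
    res$train_accuracy[i] <-
      mean(predict(model, x_train) == labels_train)
    res$val_accuracy[i] <-
      mean(predict(model, x_val) == labels_val)
  }
  ord <- order(
    -res$val_accuracy, -res$train_accuracy, res$C, res$gamma
  )
  best <- res[ord[1L], ]
  model <- rbf_svc(x_train, labels_train,
    C = best$C, gamma = best$gamma, tol = tol, max_iter = max_iter
  )
  structure(list(results = res, best = best, model = model),
    class = "svc_grid_search"
  )
}

#' @export
print.svc_grid_search <- function(x, ...) {
  cat(sprintf(
    "<svc_grid_search> %d cells; best C = %.3g, gamma = %.3g (train %.1f%%, validation %.1f%%)\n",
    nrow(x$results), x$best$C, x$best$gamma,
    100 * x$best$train_accuracy, 100 * x$best$val_accuracy
  ))
  invisible(x)
}

#' Serialise a fitted classifier to a flat text file
#' @param model an `rbf_svc` model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svc <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("classes: %s", paste(model$classes, collapse = " ")),
    sprintf("C: %s", format(model$C, digits = 17)),
    sprintf("gamma: %s", format(model$gamma, digits = 17)),
    sprintf("dim: %d", model$dim)
  ), con)
  for (m in model$machines) {
    writeLines(c(
      sprintf("machine: %d %d", m$class_pair[["positive"]], m$class_pair[["negative"]]),
      sprintf("bias: %s", format(m$bias, digits = 17)),
      sprintf("n_sv: %d", nrow(m$support_vectors))
    ), con)
    for (i in seq_len(nrow(m$support_vectors))) {
      writeLines(paste(
        format(c(m$dual_coef[i], m$support_vectors[i, ]), digits = 17),
        collapse = " "
      ), con)
    }
  }
  invisible(path)
}

#' Read a classifier written by [write_svc()]
#' @param path input path.
#' @return An `rbf_svc` model.
#' @export
read_svc <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) trimws(sub("^[^:]*:", "", grep(paste0("^", key, ":"), lines, value = TRUE)[1L]))
  classes <- as.integer(strsplit(hdr("classes"), " +")[[1L]])
  C <- as.numeric(hdr("C"))
  gamma <- as.numeric(hdr("gamma"))
  dm <- as.integer(hdr("dim"))
  starts <- grep("^machine:", lines)
  machines <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    at <- starts[k]
    pair <- as.integer(strsplit(trimws(sub("^machine:", "", lines[at])), " +")[[1L]])
    bias <- as.numeric(sub("^bias:", "", lines[at + 1L]))
    n_sv <- as.integer(sub("^n_sv:", "", lines[at + 2L]))
    rows <- lines[(at + 3L):(at + 2L + n_sv)]
    vals <- t(vapply(strsplit(trimws(rows), " +"), as.numeric, numeric(dm + 1L)))
    vals <- matrix(vals, n_sv, dm + 1L)
    machines[[k]] <- structure(list(
      support_vectors = vals[, -1L, drop = FALSE],
      dual_coef = vals[, 1L],
      bias = bias, gamma = gamma, cost = C,
      class_pair = c(positive = pair[1L], negative = pair[2L])
    ), class = "svc_binary")
  }
  structure(list(
    machines = machines, classes = classes, C = C, gamma = gamma, dim = dm
  ), class = "rbf_svc")
}
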