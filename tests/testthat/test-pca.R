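test_that("PCA matches an independent covariance eigendecomposition", {
  set.seed(4)
  X <- matrix(rnorm(20), 5, 4)
  k <- 3
  model <- fit_pca(X, k = k)

  # brute-force oracle: eigenvectors of the sample covariance
  S <- stats::cov(X) * (nrow(X) - 1) / nrow(X) # scaling irrelevant to vectors
  eig <- eigen(S, symmetric = TRUE)
  for (j in seq_len(k)) {
    v <- eig$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v # same sign convention
    expect_equal(model$loadings[, j], v, tolerance = 1e-8)
  }
  expect_equal(
    model$explained,
    (eig$values / sum(eig$values))[seq_len(k)],
    tolerance = 1e-8
  )
  expect_equal(crossprod(model$loadings), diag(k), tolerance = 1e-8)
  expect_true(all(diff(model$explained) <= 1e-12))
})

test_that("rank-1 data loads entirely on the first component", {
  t_vals <- seq(-2, 2, length.out = 6)
  X <- outer(t_vals, c(1, -2, 0.5)) # exactly on a line in band space
  model <- fit_pca(X, k = 2)
  expect_equal(model$explained[1], 1, tolerance = 1e-10)
})

test_that("full-rank reconstruction is the identity", {
  set.seed(9)
  X <- matrix(rnorm(6 * 4), 6, 4)
  k <- min(nrow(X) - 1, ncol(X))
  model <- fit_pca(X, k = k)
  scores <- transform_pca(model, X)
  recon <- sweep(scores %*% t(model$loadings), 2, model$mean, "+")
  expect_equal(recon, X, tolerance = 1e-8)
  # training scores are column-wise uncorrelated
  cv <- crossprod(scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # the training mean projects to the origin
  expect_equal(as.numeric(transform_pca(model, model$mean)), rep(0, k))
})

test_that("degenerate inputs and bad arguments are rejected", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fit_pca(X, k = 4), "between 1 and")
  expect_error(fit_pca(matrix(1, 5, 3), k = 1), "zero variance")
  expect_error(fit_pca(X[1, , drop = FALSE], k = 1), "at least 2")
  model <- fit_pca(X, k = 2)
  expect_error(transform_pca(model, matrix(0, 2, 5)), "band count")
})

test_that("score images place scores at pixel coordinates", {
  set.seed(10)
  grp <- rbind(
    matrix(rnorm(40, 0, 0.1), 10, 4),
    matrix(rnorm(40, 3, 0.1), 10, 4)
  )
  model <- fit_pca(grp, k = 2)
  px <- structure(list(
    spectra = grp,
    wavelengths = c(500, 600, 700, 800),
    coords = cbind(rep(1:5, 4), rep(1:4, each = 5)),
    sample_id = NULL, label = NULL
  ), class = "pixel_spectra")
  img <- score_image(px, model, 1, c(6, 5))
  expect_equal(sum(!is.na(img)), 20L)
  expect_true(is.na(img[6, 5])) # background flagged

  # PC1 separates the two pixel groups: between > within variance
  s1 <- transform_pca(model, grp)[, 1]
  within <- stats::var(s1[1:10]) + stats::var(s1[11:20])
  between <- (mean(s1[1:10]) - mean(s1[11:20]))^2
  expect_gt(between, within)

  one <- px
  one$spectra <- px$spectra[1, , drop = FALSE]
  one$coords <- px$coords[1, , drop = FALSE]
  img1 <- score_image(one, model, 1, c(6, 5))
  expect_equal(sum(is.finite(img1)), 1L)
  expect_error(score_image(px, model, 3, c(6, 5)), "pc_index")
  expect_error(score_image(px, model, 1, c(2, 2)), "outside")
})

test_that("the first ten PCs dominate pooled preprocessed pixel spectra", {
  p <- scene_params(image_rows = 32, image_cols = 32, leaf_count = 2)
  pooled <- do.call(rbind, lapply(1:3, function(label) {
    sc <- simulate_scene(label, p, seed = 400 + label)
    refl <- calibrate_reflectance(sc$raw, sc$dark, sc$white)
    preprocess_pixels(crop_bands(extract_pixel_spectra(refl, sc$truth)))$spectra
  }))
  model <- fit_pca(pooled, k = 10)
  # the generator's structural variance (treatment shifts + pixel scatter)
  # is low-rank, so ten components carry essentially all of it; what they
  # cannot carry is the residual smoothed pixel noise, which caps the
  # explained share just under 99% at the default noise level
  expect_gt(sum(model$explained), 0.98)
  expect_gt(model$explained[1], 0.5) # scatter/shift axis dominates
})

test_that("PCA models survive a flat-text round-trip", {
  set.seed(12)
  model <- fit_pca(matrix(rnorm(60), 10, 6), k = 3)
  tmp <- withr::local_tempfile()
  write_pca(model, tmp)
  back <- read_pca(tmp)
  expect_equal(back$mean, model$mean)
  expect_equal(back$loadings, unname(model$loadings))
  expect_equal(back$explained, model$explained)
})
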