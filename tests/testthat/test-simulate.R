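test_that("base vegetation curve has the expected landmarks and no randomness", {
  wl <- scene_wavelengths(scene_params())
  r <- base_vegetation_spectrum(wl)
  at <- function(nm) r[which.min(abs(wl - nm))]
  expect_gt(at(550), at(680)) # green peak above chlorophyll dip
  expect_equal(at(900), 0.50, tolerance = 0.02) # NIR plateau
  expect_true(all(r > 0 & r < 1))
  expect_identical(r, base_vegetation_spectrum(wl)) # deterministic
})

test_that("treatment spectra apply the visible and NIR shifts", {
  p <- scene_params()
  wl <- scene_wavelengths(p)
  ck <- treatment_spectrum(1, p, wl)
  q <- treatment_spectrum(2, p, wl)
  s <- treatment_spectrum(3, p, wl)

  # CK has zero shifts, so it equals the base curve
  expect_equal(ck, base_vegetation_spectrum(wl))

  vis <- wl >= 434 & wl <= 700
  nir <- wl >= 750 & wl <= 953
  expect_equal(mean((q - ck)[vis]), 0.04, tolerance = 0.005)
  expect_equal(mean((q - ck)[nir]), -0.05, tolerance = 0.005)
  # treated groups mutually closer than either is to the control
  expect_true(all(abs(q - s)[vis] < abs(q - ck)[vis]))
  expect_true(all(abs(q - s)[nir] < abs(q - ck)[nir]))
  expect_error(treatment_spectrum(4, p), "label")
})

test_that("noiseless scenes invert the calibration equation exactly", {
  p <- noiseless_params()
  sc <- simulate_scene(2, p, seed = 42)
  refl <- calibrate_reflectance(sc$raw, sc$dark, sc$white)
  target <- treatment_spectrum(2, p)
  leaf <- which(sc$truth, arr.ind = TRUE)
  for (i in c(1L, nrow(leaf))) {
    expect_equal(
      refl$data[leaf[i, 1], leaf[i, 2], ],
      target,
      tolerance = 1e-10
    )
  }
  bg <- which(!sc$truth, arr.ind = TRUE)[1, ]
  expect_equal(refl$data[bg[1], bg[2], ], rep(p$background_reflectance, p$n_bands),
    tolerance = 1e-10
  )
})

test_that("scene generation is a pure function of (params, seed)", {
  p <- scene_params(image_rows = 32, image_cols = 32)
  a <- simulate_scene(1, p, seed = 99)
  b <- simulate_scene(1, p, seed = 99)
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_scene(1, p, seed = 100)
  expect_false(identical(a$raw$data, c$raw$data))
})

test_that("rasterised leaf masks agree with the analytic area bookkeeping", {
  rel_err <- vapply(1:8, function(s) {
    sc <- simulate_scene(1, scene_params(), seed = s)
    f_mask <- sum(sc$truth) / length(sc$truth)
    f_analytic <- sc$analytic_leaf_area / length(sc$truth)
    abs(f_mask - f_analytic) / f_analytic
  }, numeric(1))
  expect_lt(mean(rel_err), 0.02)
})

test_that("impossible leaf layouts raise a generation error", {
  p <- scene_params(image_rows = 16, image_cols = 16, leaf_count = 40)
  expect_error(simulate_scene(1, p, seed = 1), "non-overlapping leaves")
})

test_that("dataset manifests are balanced with distinct derived seeds", {
  d <- simulate_dataset(2, scene_params(image_rows = 24, image_cols = 24), seed = 1)
  expect_length(d$scenes, 6L)
  expect_identical(d$labels, rep(1:3, each = 2L))
  expect_identical(anyDuplicated(d$manifest$seed), 0L)
  # scenes from disjoint master seeds never coincide
  d2 <- simulate_dataset(2, scene_params(image_rows = 24, image_cols = 24), seed = 2)
  expect_length(intersect(d$manifest$seed, d2$manifest$seed), 0L)
  expect_false(identical(d$scenes[[1]]$raw$data, d2$scenes[[1]]$raw$data))
  expect_error(dataset_manifest(1), ">= 2")
})

test_that("group mean spectra reproduce the treatment contrast pattern", {
  p <- scene_params(image_rows = 32, image_cols = 32, leaf_count = 2)
  wl <- scene_wavelengths(p)
  group_mean <- function(label) {
    sp <- vapply(1:4, function(i) {
      sc <- simulate_scene(label, p, seed = 100 * label + i)
      refl <- calibrate_reflectance(sc$raw, sc$dark, sc$white)
      mean_spectrum(extract_pixel_spectra(refl, sc$truth))
    }, numeric(p$n_bands))
    rowMeans(sp)
  }
  ck <- group_mean(1); q <- group_mean(2); s <- group_mean(3)
  vis <- wl >= 434 & wl <= 700
  nir <- wl >= 750 & wl <= 953
  expect_lt(mean(ck[vis]), mean(q[vis]))
  expect_lt(mean(ck[vis]), mean(s[vis]))
  expect_gt(mean(ck[nir]), mean(q[nir]))
  expect_gt(mean(ck[nir]), mean(s[nir]))
  expect_lt(mean(abs(q - s)[vis]), mean(abs(ck - q)[vis]))
  expect_lt(mean(abs(q - s)[nir]), mean(abs(ck - q)[nir]))
})
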