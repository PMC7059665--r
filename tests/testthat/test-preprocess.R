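test_that("segmentation recovers the leaf mask", {
  # noiseless: NDVI separates leaf and background exactly
  p <- noiseless_params()
  sc <- simulate_scene(1, p, seed = 3)
  refl <- calibrate_reflectance(sc$raw, sc$dark, sc$white)
  expect_identical(segment_plant(refl), sc$truth)

  # default noise: high overlap with the ground truth
  sc2 <- simulate_scene(2, scene_params(), seed = 7)
  refl2 <- calibrate_reflectance(sc2$raw, sc2$dark, sc2$white)
  mask2 <- segment_plant(refl2)
  jaccard <- sum(mask2 & sc2$truth) / sum(mask2 | sc2$truth)
  expect_gte(jaccard, 0.95)

  # flat background-only cube has no vegetation signal
  flat <- hyper_cube(
    array(0.03, c(8, 8, 3)), c(600, 700, 850)
  )
  expect_error(segment_plant(flat), "empty mask")
})

test_that("pixel extraction follows scan order and records coordinates", {
  cube <- tiny_cube(3, 3, wl = c(500, 600, 700))
  mask <- matrix(FALSE, 3, 3)
  mask[1, 2] <- mask[2, 1] <- mask[3, 3] <- TRUE
  px <- extract_pixel_spectra(cube, mask)
  expect_equal(nrow(px$spectra), 3L)
  expect_equal(px$coords, rbind(c(1, 2), c(2, 1), c(3, 3))) # row-major
  for (i in 1:3) {
    expect_equal(px$spectra[i, ], cube$data[px$coords[i, 1], px$coords[i, 2], ])
  }
  full <- extract_pixel_spectra(cube, matrix(TRUE, 3, 3))
  expect_equal(nrow(full$spectra), 9L)
  expect_error(extract_pixel_spectra(cube, matrix(TRUE, 2, 3)), "dimensions")
  expect_error(extract_pixel_spectra(cube, matrix(FALSE, 3, 3)), "no pixels")
})

test_that("band cropping covers the requested window", {
  p <- scene_params()
  wl <- scene_wavelengths(p)
  px <- structure(list(
    spectra = matrix(rnorm(2 * p$n_bands), 2, p$n_bands),
    wavelengths = wl, coords = rbind(c(1, 1), c(1, 2)),
    sample_id = NULL, label = NULL
  ), class = "pixel_spectra")

  cropped <- crop_bands(px)
  expect_equal(ncol(cropped$spectra), 410L) # the analysed 434-953 nm window
  expect_true(min(cropped$wavelengths) <= 434 && max(cropped$wavelengths) >= 953)

  # idempotent at the same limits
  again <- crop_bands(cropped)
  expect_identical(again$spectra, cropped$spectra)

  # degenerate window on an existing band centre -> exactly that band
  one <- crop_bands(px, wl[100], wl[100])
  expect_equal(ncol(one$spectra), 1L)
  expect_equal(one$wavelengths, wl[100])

  expect_error(crop_bands(px, 900, 500), "exceed")
  expect_error(crop_bands(px, 2000, 2100), "outside")
})

test_that("wavelet denoising is an idempotent projection that keeps constants", {
  n <- 410
  expect_equal(wavelet_denoise(rep(0.3, n)), rep(0.3, n), tolerance = 1e-10)

  wl <- seq(434, 953, length.out = n)
  clean <- base_vegetation_spectrum(wl)
  set.seed(8)
  noisy <- clean + rnorm(n, 0, 0.01)
  den <- wavelet_denoise(noisy)
  # closer to the clean signal than the input is
  expect_lt(sqrt(sum((den - clean)^2)), sqrt(sum((noisy - clean)^2)))
  # high-frequency alternating perturbations are removed almost entirely
  pert <- clean + 0.02 * cos(pi * seq_len(n))
  expect_lt(
    sqrt(sum((wavelet_denoise(pert) - clean)^2)),
    0.2 * sqrt(sum((pert - clean)^2))
  )
  # projection: denoise(denoise(x)) == denoise(x)
  expect_lt(sqrt(sum((wavelet_denoise(den) - den)^2)), 1e-6 * sqrt(sum(noisy^2)))

  expect_error(wavelet_denoise(rnorm(50)), "filter support")
  # matrix input denoises rows
  M <- rbind(noisy, clean)
  expect_equal(wavelet_denoise(M)[1, ], den)
})

test_that("moving average shrinks symmetrically at the edges", {
  expect_equal(moving_average(rep(2.5, 20)), rep(2.5, 20))
  x <- rnorm(15)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(1:7, 7)[4], 4) # mean of 1..7
  expect_equal(moving_average(1:7, 7)[1], 1) # edge window shrinks to width 1
  expect_equal(moving_average(1:7, 7)[2], 2) # width 3: mean(1,2,3)
  expect_error(moving_average(x, 4), "odd")
})

test_that("smoothers are translation-equivariant on interior bands", {
  wl <- seq(434, 953, length.out = 410)
  x <- treatment_spectrum(2, scene_params(), wl)
  inner <- 40:370
  # moving average: exact interior equivariance under shift by one band
  xs <- c(x[-1], x[410])
  expect_equal(moving_average(xs)[inner], moving_average(x)[inner + 1], tolerance = 1e-12)
  # wavelet space is invariant under shifts by the level-3 lattice step (8)
  xs8 <- c(x[-(1:8)], rep(x[410], 8))
  d <- wavelet_denoise(x)
  d8 <- wavelet_denoise(xs8)
  expect_equal(d8[inner], d[inner + 8], tolerance = 1e-3)
})

test_that("mean spectra are pixel-permutation-invariant band means", {
  px <- structure(list(
    spectra = rbind(c(1, 2, 3), c(3, 4, 5)),
    wavelengths = c(500, 600, 700),
    coords = rbind(c(1, 1), c(2, 2)), sample_id = NULL, label = NULL
  ), class = "pixel_spectra")
  expect_equal(mean_spectrum(px), c(2, 3, 4)) # (a + b) / 2
  one <- px; one$spectra <- px$spectra[1, , drop = FALSE]
  expect_equal(mean_spectrum(one), c(1, 2, 3))
  perm <- px; perm$spectra <- px$spectra[2:1, ]
  expect_equal(mean_spectrum(perm), mean_spectrum(px))
})

test_that("the full preprocessing chain recovers a noiseless scene", {
  p <- noiseless_params()
  sc <- simulate_scene(3, p, seed = 21)
  refl <- calibrate_reflectance(sc$raw, sc$dark, sc$white)
  mask <- segment_plant(refl)
  px <- preprocess_pixels(crop_bands(extract_pixel_spectra(refl, mask)))
  recovered <- mean_spectrum(px)
  target <- treatment_spectrum(3, p, px$wavelengths)
  rmse <- sqrt(mean((recovered - target)^2))
  expect_lt(rmse, 1e-3)
})
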