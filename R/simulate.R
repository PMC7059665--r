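# Synthetic treatment-structured vegetation scenes.
#
# The generator emulates the study conditions the pipeline was designed for:
# 512 uniformly spaced bands over 380-1030 nm, leaf-shaped regions on a dark
# background, and three treatment groups -- untreated control (CK = 1),
# herbicide-stressed (Q = 2) and salicylic-acid-rescued (S = 3) -- where the
# control has lower visible (434-700 nm) and higher near-infrared
# (750-953 nm) reflectance than the two treated groups, and the two treated
# groups are mutually much closer than either is to the control.

#' Scene generator parameters
#'
#' Bundles every knob of the synthetic-scene generator. The defaults are the
#' study conditions the rest of the package is tested under; see the methods
#' vignette for the reasoning behind each value.
#'
#' @param n_bands number of spectral bands.
#' @param wl_min,wl_max wavelength range in nm (band centres are uniformly
#'   spaced over `[wl_min, wl_max]` inclusive).
#' @param visible_shift named additive reflectance offsets per treatment on
#'   434-700 nm (`CK`, `Q`, `S`).
#' @param nir_shift named additive offsets per treatment on 750-953 nm.
#' @param pixel_noise_sd per-pixel, per-band Gaussian reflectance noise sd.
#' @param scatter_slope_sd,scatter_offset_sd per-pixel multiplicative /
#'   additive scatter sd (one draw per pixel, applied across all bands).
#' @param leaf_count number of elliptical leaves per scene.
#' @param image_rows,image_cols scene size in pixels.
#' @param background_reflectance flat background reflectance.
#' @param dark_mean,dark_sd,white_mean,white_sd reference-frame count levels.
#' @param shot_noise_scale raw-domain noise sd is
#'   `shot_noise_scale * sqrt(counts)` (0 disables it).
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(n_bands = 512L,
                         wl_min = 380, wl_max = 1030,
                         visible_shift = c(CK = 0, Q = 0.04, S = 0.03),
                         nir_shift = c(CK = 0, Q = -0.05, S = -0.04),
                         pixel_noise_sd = 0.01,
                         scatter_slope_sd = 0.05,
                         scatter_offset_sd = 0.01,
                         leaf_count = 3L,
                         image_rows = 64L, image_cols = 64L,
                         background_reflectance = 0.03,
                         dark_mean = 100, dark_sd = 2,
                         white_mean = 3000, white_sd = 20,
                         shot_noise_scale = 0.2) {
  p <- list(
    n_bands = as.integer(n_bands), wl_min = wl_min, wl_max = wl_max,
    visible_shift = visible_shift, nir_shift = nir_shift,
    pixel_noise_sd = pixel_noise_sd,
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    leaf_count = as.integer(leaf_count),
    image_rows = as.integer(image_rows), image_cols = as.integer(image_cols),
    background_reflectance = background_reflectance,
    dark_mean = dark_mean, dark_sd = dark_sd,
    white_mean = white_mean, white_sd = white_sd,
    shot_noise_scale = shot_noise_scale
  )
  stopifnot(
    p$n_bands >= 2L, p$wl_max > p$wl_min,
    length(p$visible_shift) == 3L, length(p$nir_shift) == 3L,
    p$leaf_count >= 1L, p$image_rows >= 8L, p$image_cols >= 8L
  )
  class(p) <- "scene_params"
  p
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf(
    "<scene_params> %d bands %g-%g nm, %dx%d px, %d leaves\n",
    x$n_bands, x$wl_min, x$wl_max, x$image_rows, x$image_cols, x$leaf_count
  ))
  cat(sprintf(
    "  visible shifts: CK=%+.3f Q=%+.3f S=%+.3f | NIR shifts: CK=%+.3f Q=%+.3f S=%+.3f\n",
    x$visible_shift[1L], x$visible_shift[2L], x$visible_shift[3L],
    x$nir_shift[1L], x$nir_shift[2L], x$nir_shift[3L]
  ))
  cat(sprintf(
    "  pixel noise sd %.3g, scatter slope sd %.3g, offset sd %.3g\n",
    x$pixel_noise_sd, x$scatter_slope_sd, x$scatter_offset_sd
  ))
  invisible(x)
}

#' Wavelength axis of a parameter set
#' @param params a [scene_params()].
#' @return Numeric vector of band-centre wavelengths in nm.
#' @export
scene_wavelengths <- function(params) {
  seq(params$wl_min, params$wl_max, length.out = params$n_bands)
}

#' Deterministic base vegetation reflectance curve
#'
#' A smooth idealised green-leaf reflectance: a visible baseline of 0.08 with
#' a green-peak bump at 550 nm (height 0.07, sd 30 nm), fractional pigment
#' absorption dips at 450 nm (depth 0.42, sd 40 nm) and 680 nm (depth 0.40,
#' sd 25 nm), a logistic red edge centred at 715 nm (scale 18 nm) and a
#' near-infrared plateau at 0.50. Values are clipped to (0, 1). The curve is
#' deterministic: no randomness enters here.
#'
#' @param wavelengths wavelengths in nm (expected within 380-1030).
#' @return Reflectance values, same length as `wavelengths`.
#' @examples
#' wl <- seq(400, 1000, by = 5)
#' r <- base_vegetation_spectrum(wl)
#' plot(wl, r, type = "l", xlab = "wavelength (nm)", ylab = "reflectance")
#' @export
base_vegetation_spectrum <- function(wavelengths) {
  l <- as.numeric(wavelengths)
  vis <- 0.08 + 0.07 * exp(-(l - 550)^2 / (2 * 30^2))
  vis <- vis * (1 - 0.42 * exp(-(l - 450)^2 / (2 * 40^2)))
  vis <- vis * (1 - 0.40 * exp(-(l - 680)^2 / (2 * 25^2)))
  edge <- 1 / (1 + exp(-(l - 715) / 18))
  r <- vis * (1 - edge) + 0.50 * edge
  pmin(pmax(r, 1e-3), 1 - 1e-3)
}

# Cosine-tapered region indicator: 1 on [lo, hi], raised-cosine ramps of
# width `taper` placed OUTSIDE the interval so the full effect applies on
# every band inside [lo, hi].
.taper_weight <- function(l, lo, hi, taper = 15) {
  w <- numeric(length(l))
  w[l >= lo & l <= hi] <- 1
  up <- l > lo - taper & l < lo
  w[up] <- (1 - cos(pi * (l[up] - (lo - taper)) / taper)) / 2
  dn <- l > hi & l < hi + taper
  w[dn] <- (1 - cos(pi * ((hi + taper) - l[dn]) / taper)) / 2
  w
}

#' Treatment-specific mean reflectance spectrum
#'
#' Applies the treatment's additive visible (434-700 nm) and near-infrared
#' (750-953 nm) reflectance offsets to the base vegetation curve, with 15 nm
#' cosine-tapered transitions, and clips to (0, 1).
#'
#' @param label treatment label: 1 (CK), 2 (Q) or 3 (S).
#' @param params a [scene_params()].
#' @param wavelengths optional wavelength axis; defaults to the axis implied
#'   by `params`.
#' @return Reflectance values along the wavelength axis.
#' @export
treatment_spectrum <- function(label, params = scene_params(),
                               wavelengths = scene_wavelengths(params)) {
  label <- .check_label(label)
  l <- as.numeric(wavelengths)
  r <- base_vegetation_spectrum(l) +
    params$visible_shift[label] * .taper_weight(l, 434, 700) +
    params$nir_shift[label] * .taper_weight(l, 750, 953)
  pmin(pmax(r, 1e-3), 1 - 1e-3)
}

.check_label <- function(label) {
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || !label %in% 1:3) {
    stop("treatment label must be 1 (CK), 2 (Q) or 3 (S)", call. = FALSE)
  }
  label
}

#' Treatment label names
#' @return `c("CK", "Q", "S")`
#' @export
treatment_levels <- function() c("CK", "Q", "S")

# Place `leaf_count` non-overlapping elongated ellipses; returns the logical
# mask plus the summed analytic ellipse area for bookkeeping.
.place_leaves <- function(params, max_tries = 200L) {
  nr <- params$image_rows
  nc <- params$image_cols
  mask <- matrix(FALSE, nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  placed <- 0L
  analytic_area <- 0
  tries <- 0L
  while (placed < params$leaf_count) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        "could not place %d non-overlapping leaves in %d tries",
        params$leaf_count, max_tries
      ), call. = FALSE)
    }
    a <- stats::runif(1, 10, 14) * min(nr, nc) / 64 # major semi-axis (px)
    b <- stats::runif(1, 3.5, 5) * min(nr, nc) / 64 # minor semi-axis (px)
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, a + 1, nr - a - 1)
    cy <- stats::runif(1, a + 1, nc - a - 1)
    dx <- rows - cx
    dy <- cols - cy
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside) || any(mask & inside)) next
    mask <- mask | inside
    analytic_area <- analytic_area + pi * a * b
    placed <- placed + 1L
  }
  list(mask = mask, analytic_area = analytic_area)
}

#' Simulate one hyperspectral scene
#'
#' Generates a raw-count cube plus dark and white reference frames such that
#' two-point calibration recovers the underlying reflectance. Leaf pixels
#' carry the treatment spectrum distorted by per-pixel multiplicative slope
#' and additive offset scatter and per-band Gaussian noise; the background is
#' flat at `background_reflectance` plus the same per-band noise. The
#' reflectance scene is then inverted through `raw = R * (W - B) + B` with
#' synthetic dark/white frames and optional shot-like noise, so
#' [calibrate_reflectance()] is exercised on the main analysis path. Fully
#' reproducible from `seed`.
#'
#' @param label treatment label (1 = CK, 2 = Q, 3 = S).
#' @param params a [scene_params()].
#' @param seed integer seed; every random draw derives from it.
#' @return A list of class `scene`: `raw` (raw `hyper_cube`), `dark`,
#'   `white` (reference frames), `truth` (logical leaf mask), `label`, and
#'   `analytic_leaf_area` (summed exact ellipse area in px).
#' @export
simulate_scene <- function(label, params = scene_params(), seed = 1L) {
  label <- .check_label(label)
  wl <- scene_wavelengths(params)
  nb <- params$n_bands
  nr <- params$image_rows
  nc <- params$image_cols
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  leaves <- .place_leaves(params)
  mask <- leaves$mask
  n_leaf <- sum(mask)

  target <- treatment_spectrum(label, params, wl)
  refl <- array(params$background_reflectance, c(nr, nc, nb))
  # per-pixel scatter on leaf pixels: R_px = target * (1 + slope) + offset
  slope <- stats::rnorm(n_leaf, 0, params$scatter_slope_sd)
  offset <- stats::rnorm(n_leaf, 0, params$scatter_offset_sd)
  leaf_idx <- which(mask) # column-major pixel indices
  for (b in seq_len(nb)) {
    plane <- refl[, , b]
    plane[leaf_idx] <- target[b] * (1 + slope) + offset
    refl[, , b] <- plane
  }
  if (params$pixel_noise_sd > 0) {
    refl <- refl + array(stats::rnorm(nr * nc * nb, 0, params$pixel_noise_sd),
      c(nr, nc, nb))
  }

  dark <- matrix(
    params$dark_mean + stats::rnorm(nc * nb, 0, params$dark_sd), nc, nb
  )
  white <- matrix(
    params$white_mean + stats::rnorm(nc * nb, 0, params$white_sd), nc, nb
  )
  raw <- array(0, c(nr, nc, nb))
  for (b in seq_len(nb)) {
    raw[, , b] <- sweep(
      sweep(refl[, , b, drop = TRUE], 2L, white[, b] - dark[, b], "*"),
      2L, dark[, b], "+"
    )
  }
  if (params$shot_noise_scale > 0) {
    raw <- raw + stats::rnorm(length(raw), 0,
      params$shot_noise_scale * sqrt(pmax(raw, 0)))
  }
  structure(list(
    raw = hyper_cube(raw, wl, kind = "raw"),
    dark = reference_frame(dark, "dark"),
    white = reference_frame(white, "white"),
    truth = mask,
    label = label,
    analytic_leaf_area = leaves$analytic_area
  ), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> label %d (%s), %d leaf pixels\n",
    x$label, treatment_levels()[x$label], sum(x$truth)
  ))
  invisible(x)
}

#' Manifest of a balanced synthetic dataset
#'
#' Deterministically derives one scene seed per sample from a master seed.
#'
#' @param n_per_group scenes per treatment group (>= 2).
#' @param seed master seed.
#' @return data.frame with columns `id`, `label`, `seed`.
#' @export
dataset_manifest <- function(n_per_group, seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("`n_per_group` must be >= 2", call. = FALSE)
  n <- 3L * n_per_group
  labels <- rep(1:3, each = n_per_group)
  scene_seed <- (as.numeric(seed) + 7919 * seq_len(n)) %% .Machine$integer.max
  data.frame(
    id = sprintf("scene_%03d", seq_len(n)),
    label = labels,
    seed = as.integer(scene_seed)
  )
}

#' Simulate a balanced labelled dataset of scenes
#'
#' @inheritParams dataset_manifest
#' @param params a [scene_params()].
#' @return List with `scenes` (list of [simulate_scene()] results),
#'   `labels`, and the `manifest` data.frame. For large datasets prefer
#'   iterating over [dataset_manifest()] and generating scenes one at a time.
#' @export
simulate_dataset <- function(n_per_group, params = scene_params(), seed = 1L) {
  man <- dataset_manifest(n_per_group, seed)
  scenes <- lapply(seq_len(nrow(man)), function(i) {
    simulate_scene(man$label[i], params, man$seed[i])
  })
  list(scenes = scenes, labels = man$label, manifest = man)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
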