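# End-to-end pipeline: simulate -> calibrate -> preprocess -> split ->
# train (full-spectrum and PC-score variants) -> evaluate -> map.

#' Pipeline configuration
#'
#' Collects every constant of the end-to-end run. The defaults are the
#' pipeline's standard operating point: 434-953 nm analysis window,
#' Daubechies-9 level-3 wavelet denoising with 7-point moving-average
#' smoothing, per-class 4:1:1 train/validation/test split, ten PC-score
#' features, and the 17 x 17 decade grid `10^N, N = -8..8` for the SVC
#' search.
#'
#' @param n_per_group scenes per treatment group.
#' @param scene a [scene_params()] object.
#' @param lo_nm,hi_nm analysed wavelength window in nm.
#' @param window moving-average window (odd).
#' @param wavelet_level wavelet decomposition level.
#' @param split_mode `"4:1:1"` (train/validation/test) or `"ks_2to1"`
#'   (Kennard-Stone 2:1 calibration/prediction; the prediction set then
#'   serves as the validation set for model selection).
#' @param n_pc number of PC-score features.
#' @param grid_n_lo,grid_n_hi decade exponent range of the grid search.
#' @param ndvi_threshold,min_component segmentation parameters.
#' @param seed master seed; every random draw derives from it.
#' @param outdir optional directory for artifacts (created if needed).
#' @param write_scenes if `TRUE` (and `outdir` is set) every simulated
#'   scene is written as an ENVI cube.
#' @param make_maps if `TRUE`, pixel-wise prediction maps are computed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 40L,
                            scene = scene_params(),
                            lo_nm = 434, hi_nm = 953,
                            window = 7L, wavelet_level = 3L,
                            split_mode = c("4:1:1", "ks_2to1"),
                            n_pc = 10L,
                            grid_n_lo = -8L, grid_n_hi = 8L,
                            ndvi_threshold = 0.4, min_component = 20L,
                            seed = 1L,
                            outdir = NULL,
                            write_scenes = FALSE,
                            make_maps = TRUE) {
  split_mode <- match.arg(split_mode)
  structure(list(
    n_per_group = as.integer(n_per_group), scene = scene,
    lo_nm = lo_nm, hi_nm = hi_nm,
    window = as.integer(window), wavelet_level = as.integer(wavelet_level),
    split_mode = split_mode, n_pc = as.integer(n_pc),
    grid_n_lo = as.integer(grid_n_lo), grid_n_hi = as.integer(grid_n_hi),
    ndvi_threshold = ndvi_threshold, min_component = as.integer(min_component),
    seed = as.integer(seed), outdir = outdir,
    write_scenes = isTRUE(write_scenes), make_maps = isTRUE(make_maps)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; scene-generator fields
#' go under a `scene:` block with the argument names of [scene_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  scene_args <- raw$scene
  if (!is.null(scene_args)) {
    for (nm in c("visible_shift", "nir_shift")) {
      if (!is.null(scene_args[[nm]])) {
        scene_args[[nm]] <- unlist(scene_args[[nm]])
      }
    }
  }
  scene <- do.call(scene_params, if (is.null(scene_args)) list() else scene_args)
  raw$scene <- NULL
  do.call(pipeline_config, c(raw, list(scene = scene)))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> %d scenes/group, window %g-%g nm, split %s, %d PCs, grid 10^(%d..%d), seed %d\n",
    x$n_per_group, x$lo_nm, x$hi_nm, x$split_mode, x$n_pc,
    x$grid_n_lo, x$grid_n_hi, x$seed
  ))
  invisible(x)
}

#' Run the full analysis pipeline on synthetic scenes
#'
#' Simulates the balanced dataset, calibrates each raw cube to reflectance,
#' segments plant pixels, preprocesses the pixel spectra (crop to the
#' analysed window, wavelet denoise, moving-average smooth) and averages
#' them into sample spectra; splits the samples; trains RBF support vector
#' classifiers by decade grid search with full-spectrum features and with
#' PC-score features; evaluates accuracy and Cohen's kappa per set; and
#' (optionally) classifies every plant pixel of every scene into a
#' prediction map. Bit-reproducible from the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `leafspec_run`; see Details.
#' @details The returned object holds `spectra` (sample-by-band matrix),
#'   `labels`, `split`, `grid` (per feature mode, the grid-search object),
#'   `metrics` (per feature mode, a [metrics_report()] data.frame), `pca`,
#'   `maps` (per scene: fractions, majority category), `map_agreement`
#'   (fraction of scenes whose majority pixel category equals the true
#'   treatment), `pixel_summary`, and `feature_dims`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- character()
  man <- dataset_manifest(config$n_per_group, config$seed)
  n <- nrow(man)
  wl <- scene_wavelengths(config$scene)

  spectra <- NULL
  pixel_store <- if (config$make_maps) vector("list", n) else NULL
  for (i in seq_len(n)) {
    sc <- .stage(
      sprintf("simulate scene %s", man$id[i]), stages,
      simulate_scene(man$label[i], config$scene, man$seed[i])
    )
    refl <- calibrate_reflectance(sc$raw, sc$dark, sc$white)
    mask <- segment_plant(refl, config$ndvi_threshold, config$min_component)
    px <- extract_pixel_spectra(refl, mask,
      sample_id = man$id[i], label = man$label[i]
    )
    px <- crop_bands(px, config$lo_nm, config$hi_nm)
    px <- preprocess_pixels(px, config$window, config$wavelet_level)
    if (is.null(spectra)) {
      spectra <- matrix(NA_real_, n, ncol(px$spectra))
      colnames(spectra) <- sprintf("%.2f", px$wavelengths)
    }
    spectra[i, ] <- mean_spectrum(px)
    if (config$make_maps) {
      pixel_store[[i]] <- list(spectra = px$spectra, coords = px$coords)
    }
    if (config$write_scenes && !is.null(config$outdir)) {
      dir.create(file.path(config$outdir, "scenes"), showWarnings = FALSE, recursive = TRUE)
      write_envi_cube(sc$raw, file.path(config$outdir, "scenes", man$id[i]), "bsq")
    }
  }
  labels <- man$label

  split <- if (config$split_mode == "4:1:1") {
    split_4_1_1(labels, spectra)
  } else {
    ks <- kennard_stone_split(spectra)
    structure(list(
      train = ks$calibration, validation = ks$prediction, test = ks$prediction
    ), class = "dataset_split")
  }

  pca <- fit_pca(spectra[split$train, , drop = FALSE], k = config$n_pc)
  features <- list(
    full_spectrum = spectra,
    pc10 = transform_pca(pca, spectra)
  )
  grid <- svc_grid(config$grid_n_lo, config$grid_n_hi)

  gs <- list()
  metrics <- list()
  for (mode in names(features)) {
    X <- features[[mode]]
    gs[[mode]] <- .stage(
      sprintf("grid search (%s)", mode), stages,
      svc_grid_search(
        X[split$train, , drop = FALSE], labels[split$train],
        X[split$validation, , drop = FALSE], labels[split$validation],
        grid = grid
      )
    )
    model <- gs[[mode]]$model
    metrics[[mode]] <- metrics_report(list(
      train = list(
        actual = labels[split$train],
        predicted = predict(model, X[split$train, , drop = FALSE])
      ),
      validation = list(
        actual = labels[split$validation],
        predicted = predict(model, X[split$validation, , drop = FALSE])
      ),
      test = list(
        actual = labels[split$test],
        predicted = predict(model, X[split$test, , drop = FALSE])
      )
    ))
  }

  maps <- NULL
  map_agreement <- NA_real_
  px_summary <- NULL
  if (config$make_maps) {
    model <- gs$pc10$model
    maps <- lapply(seq_len(n), function(i) {
      scores <- transform_pca(pca, pixel_store[[i]]$spectra)
      pred <- predict(model, scores)
      fr <- as.numeric(table(factor(pred, levels = model$classes))) /
        length(pred)
      names(fr) <- treatment_levels()[model$classes]
      list(
        fractions = fr,
        majority = model$classes[which.max(fr)],
        n_pixels = length(pred)
      )
    })
    majorities <- vapply(maps, function(m) m$majority, integer(1L))
    map_agreement <- mean(majorities == labels)
    fake_maps <- lapply(maps, function(m) list(fractions = m$fractions))
    px_summary <- pixel_summary(fake_maps, labels)
  }

  run <- structure(list(
    config = config,
    manifest = man,
    spectra = spectra,
    labels = labels,
    split = split,
    pca = pca,
    grid = gs,
    metrics = metrics,
    maps = maps,
    map_agreement = map_agreement,
    pixel_summary = px_summary,
    feature_dims = vapply(features, ncol, integer(1L))
  ), class = "leafspec_run")

  if (!is.null(config$outdir)) .write_run_artifacts(run)
  run
}

.stage <- function(name, stages, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

.write_run_artifacts <- function(run) {
  out <- run$config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  spec_df <- data.frame(
    sample_id = run$manifest$id, label = run$labels,
    run$spectra, check.names = FALSE
  )
  utils::write.csv(spec_df, file.path(out, "sample_spectra.csv"), row.names = FALSE)
  write_split(run$split, run$manifest$id, file.path(out, "split.csv"))
  write_pca(run$pca, file.path(out, "pca_model.txt"))
  for (mode in names(run$grid)) {
    utils::write.csv(run$grid[[mode]]$results,
      file.path(out, sprintf("gridsearch_%s.csv", mode)),
      row.names = FALSE
    )
    write_svc(run$grid[[mode]]$model, file.path(out, sprintf("svc_%s.txt", mode)))
    utils::write.csv(run$metrics[[mode]],
      file.path(out, sprintf("metrics_%s.csv", mode)),
      row.names = FALSE
    )
  }
  if (!is.null(run$maps)) {
    fr <- do.call(rbind, lapply(run$maps, function(m) m$fractions))
    utils::write.csv(
      data.frame(
        sample_id = run$manifest$id, label = run$labels,
        majority = vapply(run$maps, function(m) m$majority, integer(1L)),
        fr
      ),
      file.path(out, "map_fractions.csv"),
      row.names = FALSE
    )
    utils::write.csv(run$pixel_summary, file.path(out, "pixel_summary.csv"),
      row.names = FALSE
    )
  }
  invisible(out)
}

#' @export
print.leafspec_run <- function(x, ...) {
  cat(sprintf(
    "<leafspec_run> %d scenes (%d per group), seed %d\n",
    nrow(x$manifest), x$config$n_per_group, x$config$seed
  ))
  for (mode in names(x$metrics)) {
    m <- x$metrics[[mode]]
    cat(sprintf(
      "  %-13s (dim %3d): train %.2f%% | validation %.2f%% | test %.2f%% accuracy (kappa %.2f / %.2f / %.2f%%)\n",
      mode, x$feature_dims[[mode]],
      100 * m$accuracy[m$set == "train"],
      100 * m$accuracy[m$set == "validation"],
      100 * m$accuracy[m$set == "test"],
      100 * m$kappa[m$set == "train"],
      100 * m$kappa[m$set == "validation"],
      100 * m$kappa[m$set == "test"]
    ))
  }
  if (!is.na(x$map_agreement)) {
    cat(sprintf(
      "  prediction maps: majority category matches truth for %.1f%% of scenes\n",
      100 * x$map_agreement
    ))
  }
  invisible(x)
}
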