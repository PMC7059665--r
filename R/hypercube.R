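#' Hyperspectral cube
#'
#' A hyperspectral cube couples a 3-D array of per-pixel intensity or
#' reflectance, indexed `(row, col, band)`, with the wavelength (nm) of each
#' band centre and a flag saying whether the values are raw sensor counts or
#' calibrated reflectance.
#'
#' @param data 3-D numeric array, dimensions `rows x cols x bands`.
#' @param wavelengths strictly increasing numeric vector of band-centre
#'   wavelengths in nm; length must equal `dim(data)[3]`.
#' @param kind `"raw"` (sensor counts) or `"reflectance"`.
#'
#' @return An object of class `hyper_cube` with elements `data`,
#'   `wavelengths` and `kind`.
#' @examples
#' cube <- hyper_cube(array(runif(2 * 2 * 3), c(2, 2, 3)), c(400, 500, 600))
#' dim(cube$data)
#' @export
hyper_cube <- function(data, wavelengths, kind = c("reflectance", "raw")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L]) {
    stop(sprintf(
      "wavelength count (%d) does not match band count (%d)",
      length(wavelengths), dim(data)[3L]
    ), call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(data = data, wavelengths = wavelengths, kind = kind),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind: %s\n",
    d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths), x$kind
  ))
  invisible(x)
}

#' Reference frame for reflectance calibration
#'
#' Line-scan acquisitions record a dark frame (shutter closed, reflectance
#' close to 0) and a white frame (standard tile, reflectance close to 100%)
#' as a single scan line of `cols x bands` values that is broadcast down the
#' image rows during calibration.
#'
#' @param data numeric matrix `cols x bands`, or a 3-D array with one row
#'   (`1 x cols x bands`).
#' @param role `"dark"` or `"white"`.
#' @return An object of class `reference_frame`.
#' @export
reference_frame <- function(data, role = c("dark", "white")) {
  role <- match.arg(role)
  if (is.array(data) && length(dim(data)) == 3L) {
    if (dim(data)[1L] != 1L) {
      stop("3-D reference data must have a single row (1 x cols x bands)",
        call. = FALSE
      )
    }
    data <- array(data[1L, , ], dim = dim(data)[2:3])
  }
  if (!is.matrix(data)) {
    stop("`data` must be a cols x bands matrix", call. = FALSE)
  }
  structure(list(data = data, role = role), class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat(sprintf(
    "<reference_frame> role: %s, %d cols x %d bands, mean %.1f\n",
    x$role, nrow(x$data), ncol(x$data), mean(x$data)
  ))
  invisible(x)
}

#' Calibrate raw counts to reflectance
#'
#' Converts a raw intensity cube to reflectance with the standard two-point
#' calibration `R = (I_raw - B) / (W - B)`, where `B` is the dark reference
#' and `W` the white reference, broadcast along scan lines. Elements where
#' the white and dark references coincide (|W - B| below `guard`) cannot be
#' calibrated; they are set to 0 and counted in the attached report.
#'
#' @param raw a `hyper_cube` with `kind = "raw"`.
#' @param dark,white `reference_frame` objects of matching `cols x bands`
#'   geometry (or matrices).
#' @param guard minimum |white - dark| treated as non-degenerate.
#' @param strict if `TRUE`, more than 1% degenerate elements is an error
#'   instead of a warning.
#' @return A reflectance `hyper_cube`; attribute `"calibration_report"` holds
#'   the degenerate-element count and fraction.
#' @examples
#' wl <- c(500, 600)
#' raw <- hyper_cube(array(1500, c(2, 2, 2)), wl, kind = "raw")
#' dark <- reference_frame(matrix(100, 2, 2), "dark")
#' white <- reference_frame(matrix(2900, 2, 2), "white")
#' calibrate_reflectance(raw, dark, white)$data[1, 1, ]  # 0.5 0.5
#' @export
calibrate_reflectance <- function(raw, dark, white, guard = 1e-12,
                                  strict = FALSE) {
  if (!inherits(raw, "hyper_cube")) stop("`raw` must be a hyper_cube", call. = FALSE)
  if (raw$kind != "raw") stop("`raw` must have kind = \"raw\"", call. = FALSE)
  B <- if (inherits(dark, "reference_frame")) dark$data else dark
  W <- if (inherits(white, "reference_frame")) white$data else white
  d <- dim(raw$data)
  if (!all(dim(B) == d[2:3]) || !all(dim(W) == d[2:3])) {
    stop(sprintf(
      "reference geometry (%s / %s) does not match cube cols x bands (%d x %d)",
      paste(dim(B), collapse = "x"), paste(dim(W), collapse = "x"), d[2L], d[3L]
    ), call. = FALSE)
  }
  denom <- W - B
  degenerate <- abs(denom) < guard
  n_deg <- sum(degenerate)
  frac_deg <- n_deg / length(denom)
  if (frac_deg > 0.01) {
    msg <- sprintf(
      "%.2f%% of reference elements are degenerate (white = dark)",
      100 * frac_deg
    )
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  denom[degenerate] <- 1 # placeholder; results zeroed below
  # broadcast the single-line references down the rows
  refl <- array(0, d)
  for (b in seq_len(d[3L])) {
    num <- sweep(raw$data[, , b, drop = TRUE], 2L, B[, b], "-")
    refl[, , b] <- sweep(num, 2L, denom[, b], "/")
    if (n_deg > 0L && any(degenerate[, b])) {
      refl[, degenerate[, b], b] <- 0
    }
  }
  out <- hyper_cube(refl, raw$wavelengths, kind = "reflectance")
  attr(out, "calibration_report") <- list(
    degenerate_elements = n_deg,
    degenerate_fraction = frac_deg
  )
  out
}

#' Write a calibration report as plain text
#'
#' @param cube a calibrated `hyper_cube` carrying a `"calibration_report"`
#'   attribute.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(cube, path) {
  rep <- attr(cube, "calibration_report")
  if (is.null(rep)) stop("cube carries no calibration report", call. = FALSE)
  writeLines(c(
    sprintf("degenerate_elements: %d", rep$degenerate_elements),
    sprintf("degenerate_fraction: %.6g", rep$degenerate_fraction)
  ), path)
  invisible(path)
}
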