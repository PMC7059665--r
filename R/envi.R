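# ENVI-style cube I/O: ASCII header (.hdr) + flat binary in BIL/BIP/BSQ
# interleave. Dialect: "ENVI" magic line, lowercase keys, wavelengths as a
# braced comma list in nm; reflectance stored as 32-bit float (data type 4),
# raw counts as 16-bit unsigned (data type 12). Little-endian (byte order 0).

.envi_dtypes <- list(
  `4` = list(what = "numeric", size = 4L),
  `5` = list(what = "numeric", size = 8L),
  `12` = list(what = "integer", size = 2L)
)

#' Read an ENVI-style hyperspectral cube
#'
#' Parses an ASCII ENVI header and its companion binary file and returns the
#' cube with data ordered `(row, col, band)` regardless of the stored
#' interleave.
#'
#' @param header_path path to the `.hdr` file. The binary file is found by
#'   dropping the `.hdr` extension, or from the header's `interleave`
#'   extension (`.bil`/`.bip`/`.bsq`).
#' @return A [hyper_cube()].
#' @seealso [write_envi_cube()]
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path)) {
    stop(sprintf("header file not found: %s", header_path), call. = FALSE)
  }
  hdr <- .parse_envi_header(header_path)
  for (field in c("samples", "lines", "bands", "interleave", "data type")) {
    if (is.null(hdr[[field]])) {
      stop(sprintf("ENVI header is missing required field '%s'", field),
        call. = FALSE
      )
    }
  }
  samples <- as.integer(hdr$samples) # cols
  lines <- as.integer(hdr$lines) # rows
  bands <- as.integer(hdr$bands)
  interleave <- tolower(hdr$interleave)
  if (!interleave %in% c("bil", "bip", "bsq")) {
    stop(sprintf("unsupported interleave '%s'", interleave), call. = FALSE)
  }
  if (is.null(hdr$wavelength)) {
    stop("ENVI header is missing required field 'wavelength'", call. = FALSE)
  }
  wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1L]])
  if (length(wl) != bands) {
    stop(sprintf(
      "wavelength list length (%d) contradicts declared bands (%d)",
      length(wl), bands
    ), call. = FALSE)
  }
  dt <- .envi_dtypes[[as.character(as.integer(hdr$`data type`))]]
  if (is.null(dt)) {
    stop(sprintf("unsupported data type %s", hdr$`data type`), call. = FALSE)
  }
  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) {
    stop(sprintf("binary file for %s not found", header_path), call. = FALSE)
  }
  n <- samples * lines * bands
  con <- file(bin_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
    signed = dt$size > 2L || dt$what == "numeric")
  if (length(vals) != n) {
    stop("binary file is shorter than the header declares", call. = FALSE)
  }
  # first stored index varies fastest:
  #   bsq: (col, row, band); bil: (col, band, row); bip: (band, col, row)
  cube <- switch(interleave,
    bsq = aperm(array(vals, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(vals, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(vals, c(bands, samples, lines)), c(3L, 2L, 1L))
  )
  kind <- if (!is.null(hdr$`leafspec kind`)) hdr$`leafspec kind` else {
    if (dt$size == 2L) "raw" else "reflectance"
  }
  hyper_cube(cube, wl, kind = kind)
}

#' Write an ENVI-style hyperspectral cube
#'
#' Writes an ASCII header (`<base_path>.hdr`) and the flat binary cube
#' (`<base_path>.<interleave>`). Reflectance cubes are stored as 32-bit
#' floats, raw cubes as 16-bit unsigned integers.
#'
#' @param cube a [hyper_cube()].
#' @param base_path output path without extension.
#' @param interleave `"bil"`, `"bip"` or `"bsq"`.
#' @return Named character vector with the header and binary paths, invisibly.
#' @export
write_envi_cube <- function(cube, base_path, interleave = c("bsq", "bil", "bip")) {
  if (!inherits(cube, "hyper_cube")) stop("`cube` must be a hyper_cube", call. = FALSE)
  if (length(interleave) == 1L && !interleave %in% c("bil", "bip", "bsq")) {
    stop(sprintf("invalid interleave '%s'", interleave), call. = FALSE)
  }
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  raw_kind <- cube$kind == "raw"
  dtype <- if (raw_kind) 12L else 4L
  size <- if (raw_kind) 2L else 4L
  bin_path <- paste0(base_path, ".", interleave)
  hdr_path <- paste0(bin_path, ".hdr")
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("leafspec kind = %s", cube$kind),
    sprintf(
      "wavelength = {%s}",
      paste(format(cube$wavelengths, trim = TRUE, digits = 10), collapse = ", ")
    )
  )
  ok <- tryCatch(
    {
      writeLines(hdr, hdr_path)
      TRUE
    },
    error = function(e) FALSE, warning = function(e) FALSE
  )
  if (!ok) stop(sprintf("cannot write to %s", hdr_path), call. = FALSE)
  # reorder so the first stored index varies fastest (see read_envi_cube)
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2L, 1L, 3L))),
    bil = as.vector(aperm(cube$data, c(2L, 3L, 1L))),
    bip = as.vector(aperm(cube$data, c(3L, 2L, 1L)))
  )
  con <- file(bin_path, "wb")
  on.exit(close(con))
  if (raw_kind) {
    writeBin(as.integer(round(vals)), con, size = size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = size, endian = "little")
  }
  invisible(c(header = hdr_path, binary = bin_path))
}

.parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ENVI") {
    stop("not an ENVI header (missing magic line)", call. = FALSE)
  }
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln, fixed = TRUE)) {
      i <- i + 1L
      next
    }
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("}", val, fixed = TRUE) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      val <- gsub("[{}]", "", val)
    }
    out[[key]] <- trimws(val)
    i <- i + 1L
  }
  out
}
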