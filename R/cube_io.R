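#' Write / read labeled reflectance cubes
#'
#' Two on-disk layouts are supported for an `H x W x Nlambda` reflectance
#' cube:
#'
#' * ENVI-style band-sequential (BSQ) float32 binary (`<stem>.raw`) with a
#'   plain-text `<stem>.hdr` header carrying `samples`, `lines`, `bands`,
#'   `data type = 4`, `interleave = bsq`, `byte order` and the band
#'   wavelengths;
#' * multi-page TIFF (`<stem>.tif`, one 32-bit float page per band) with a
#'   sidecar `<stem>.json` listing the band wavelengths (requires the
#'   `tiff` package).
#'
#' The integer label mask is stored alongside as `<stem>_mask.csv`
#' (comma-separated integers, one row per image row, sentinel -1 =
#' unlabeled).
#'
#' @param scene A [generate_scene()] result.
#' @param stem Path stem (no extension).
#' @return The read scene, or (invisibly) `stem` for writers.
#' @name cube_io
NULL

write_mask_csv <- function(mask, path) {
  write.table(mask, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_mask_csv <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}

#' @rdname cube_io
#' @export
write_cube_envi <- function(scene, stem) {
  cube <- scene$cube
  d <- dim(cube)
  # BSQ: full band planes in sequence; R arrays are (row, col, band)
  # column-major, so write band by band in row-major (line) order.
  con <- file(paste0(stem, ".raw"), "wb")
  on.exit(close(con), add = TRUE)
  for (b in seq_len(d[3])) {
    writeBin(as.vector(t(cube[, , b])), con, size = 4, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = {lightspd reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf(
      "wavelength = {%s}",
      paste(format(scene$wavelength_nm, trim = TRUE), collapse = ", ")
    )
  )
  writeLines(hdr, paste0(stem, ".hdr"))
  if (!is.null(scene$mask)) write_mask_csv(scene$mask, paste0(stem, "_mask.csv"))
  invisible(stem)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexpr(sprintf("%s\\s*=\\s*[0-9]+", key), txt))
    if (!length(m)) abort(sprintf("ENVI header %s: missing `%s`.", path, key))
    as.integer(sub(".*=\\s*", "", m))
  }
  wl <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  wl <- if (length(wl)) {
    as.numeric(strsplit(gsub(".*\\{|\\}", "", wl), ",")[[1]])
  } else {
    NULL
  }
  list(
    samples = get_scalar("samples"),
    lines = get_scalar("lines"),
    bands = get_scalar("bands"),
    data_type = get_scalar("data type"),
    byte_order = get_scalar("byte order"),
    wavelength = wl
  )
}

#' @rdname cube_io
#' @export
read_cube_envi <- function(stem) {
  hdr_path <- paste0(stem, ".hdr")
  raw_path <- paste0(stem, ".raw")
  if (!file.exists(hdr_path)) abort(sprintf("Missing ENVI header: %s", hdr_path))
  if (!file.exists(raw_path)) abort(sprintf("Missing ENVI data file: %s", raw_path))
  hdr <- parse_envi_header(hdr_path)
  if (hdr$data_type != 4) abort("Only float32 (ENVI data type 4) is supported.")
  n <- hdr$samples * hdr$lines * hdr$bands
  endian <- if (hdr$byte_order == 0) "little" else "big"
  v <- readBin(raw_path, "numeric", n = n, size = 4, endian = endian)
  cube <- array(0, c(hdr$lines, hdr$samples, hdr$bands))
  plane <- hdr$samples * hdr$lines
  for (b in seq_len(hdr$bands)) {
    cube[, , b] <- t(matrix(v[((b - 1) * plane + 1):(b * plane)],
                            hdr$samples, hdr$lines))
  }
  mask_path <- paste0(stem, "_mask.csv")
  structure(
    list(
      cube = cube,
      mask = if (file.exists(mask_path)) read_mask_csv(mask_path) else NULL,
      wavelength_nm = hdr$wavelength
    ),
    class = "reflectance_cube"
  )
}

#' @rdname cube_io
#' @export
write_cube_tiff <- function(scene, stem) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is required for TIFF cube output.")
  }
  d <- dim(scene$cube)
  pages <- lapply(seq_len(d[3]), function(b) scene$cube[, , b])
  tiff::writeTIFF(pages, paste0(stem, ".tif"), bits.per.sample = 32)
  jsonlite::write_json(
    list(wavelength_nm = scene$wavelength_nm),
    paste0(stem, ".json"),
    digits = NA
  )
  if (!is.null(scene$mask)) write_mask_csv(scene$mask, paste0(stem, "_mask.csv"))
  invisible(stem)
}

#' @rdname cube_io
#' @export
read_cube_tiff <- function(stem) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is required for TIFF cube input.")
  }
  tif_path <- paste0(stem, ".tif")
  if (!file.exists(tif_path)) abort(sprintf("Missing TIFF file: %s", tif_path))
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  cube <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (b in seq_along(pages)) cube[, , b] <- pages[[b]]
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  mask_path <- paste0(stem, "_mask.csv")
  structure(
    list(
      cube = cube,
      mask = if (file.exists(mask_path)) read_mask_csv(mask_path) else NULL,
      wavelength_nm = as.numeric(side$wavelength_nm)
    ),
    class = "reflectance_cube"
  )
}
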