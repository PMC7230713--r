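#' Write / read a band-sequential hypercube with an ENVI-style header
#'
#' Cubes are stored as 32-bit little-endian IEEE floats in band-sequential
#' (BSQ) order in `<path>.img`, with a plain-text `<path>.hdr` carrying
#' `samples`, `lines`, `bands`, `interleave`, `data type`, `byte order`
#' and the wavelength list — the minimal header most hyperspectral tools
#' accept.
#'
#' @param cube 3-D numeric array, rows x cols x bands.
#' @param axis Wavelength axis (nm), length = number of bands.
#' @param path Path stem; `.img` and `.hdr` are appended.
#' @return `write_envi_cube()` returns `path` invisibly;
#'   `read_envi_cube()` returns `list(cube, axis)`.
#' @export
write_envi_cube <- function(cube, axis, path) {
  stopifnot(is.array(cube), length(dim(cube)) == 3L)
  axis <- assert_axis(axis)
  d <- dim(cube)
  if (d[3] != length(axis)) stop("band count mismatch", call. = FALSE)
  # BSQ: full spatial plane per band; R arrays are already band-major in
  # the third index, so a plain aperm to (col-major within band) works
  con <- file(paste0(path, ".img"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(as.numeric(cube)), con, size = 4L, endian = "little")
  hdr <- c(
    "ENVI",
    "description = {scalespec synthetic cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(sprintf("%.6f", axis), collapse = ", "),
           "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_envi_cube
#' @export
read_envi_cube <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  grab <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) stop("missing '", key, "' in ENVI header",
                          call. = FALSE)
    sub(paste0("^", key, " *= *"), "", ln[1])
  }
  samples <- as.integer(grab("samples"))
  lines_ <- as.integer(grab("lines"))
  bands <- as.integer(grab("bands"))
  if (tolower(grab("interleave")) != "bsq") {
    stop("only BSQ interleave is supported", call. = FALSE)
  }
  wl_txt <- sub(".*\\{", "", sub("\\}.*", "", grab("wavelength")))
  axis <- as.numeric(strsplit(wl_txt, ",")[[1]])
  con <- file(paste0(path, ".img"), "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = samples * lines_ * bands, size = 4L,
                  endian = "little")
  list(cube = array(vals, dim = c(lines_, samples, bands)),
       axis = wavelength_axis(axis))
}

#' Write a scale mask as 0/1 CSV
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  utils::write.table(mask * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
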