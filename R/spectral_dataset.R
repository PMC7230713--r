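#' Spectral dataset container
#'
#' Bundles a sample-by-band reflectance matrix with its wavelength axis,
#' the paired scaling-rate responses and a body-region label. This is the
#' object every pretreatment, wavelength selector and regression routine
#' consumes.
#'
#' @param axis Wavelength axis (nm), see [wavelength_axis()].
#' @param spectra Numeric matrix, samples in rows, bands in columns.
#' @param responses Numeric vector of scaling rates, one per sample.
#'   Stored on the percent scale unless `response_unit = "fraction"`.
#' @param region Body-region label, e.g. `"back"`, `"belly"`, `"tail"`.
#' @param reflectance_unit `"percent"` (reflectance in 0-100, the corrected
#'   image convention) or `"fraction"` (0-1). Purely declarative: all
#'   downstream operations are either scale-invariant or documented
#'   per-scale.
#' @param response_unit `"percent"` or `"fraction"` for the stored rates.
#' @return An object of class `spectral_dataset`: a list with elements
#'   `axis`, `spectra`, `responses`, `region`, `reflectance_unit`,
#'   `response_unit`.
#' @examples
#' ds <- spectral_dataset(seq(400, 410, by = 2),
#'                        matrix(runif(18), 3, 6), c(10, 50, 90))
#' ds
#' @export
spectral_dataset <- function(axis, spectra, responses, region = "unknown",
                             reflectance_unit = c("percent", "fraction"),
                             response_unit = c("percent", "fraction")) {
  axis <- assert_axis(axis, min_bands = 1L)
  reflectance_unit <- match.arg(reflectance_unit)
  response_unit <- match.arg(response_unit)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (ncol(spectra) != length(axis)) {
    stop("`spectra` must have one column per axis band", call. = FALSE)
  }
  if (nrow(spectra) != length(responses)) {
    stop("row count of `spectra` must equal length of `responses`",
         call. = FALSE)
  }
  if (!all(is.finite(spectra)) || !all(is.finite(responses))) {
    stop("spectra and responses must be finite", call. = FALSE)
  }
  structure(
    list(axis = axis, spectra = spectra, responses = as.numeric(responses),
         region = as.character(region)[1L],
         reflectance_unit = reflectance_unit,
         response_unit = response_unit),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d bands (%.1f-%.1f nm), region '%s'\n",
    nrow(x$spectra), length(x$axis), min(x$axis), max(x$axis), x$region))
  cat(sprintf("  scaling rate (%s): %.2f-%.2f, sd %.3f\n", x$response_unit,
              min(x$responses), max(x$responses), stats::sd(x$responses)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$spectra)

# subset a dataset by sample rows and/or band columns (internal)
ds_subset <- function(ds, rows = NULL, bands = NULL) {
  rows <- rows %||% seq_len(nrow(ds$spectra))
  bands <- bands %||% seq_along(ds$axis)
  spectral_dataset(ds$axis[bands], ds$spectra[rows, bands, drop = FALSE],
                   ds$responses[rows], ds$region,
                   ds$reflectance_unit, ds$response_unit)
}

# swap in a transformed spectra matrix, keeping metadata (internal)
ds_with_spectra <- function(ds, spectra,
                            reflectance_unit = ds$reflectance_unit) {
  spectral_dataset(ds$axis, spectra, ds$responses, ds$region,
                   reflectance_unit, ds$response_unit)
}

#' Write / read a spectral dataset as delimited text
#'
#' The CSV layout has one header row of wavelengths (in nm, prefixed
#' `wl_`), one row per sample, and a final `scaling_rate_percent` column
#' (or `scaling_rate_fraction` when the dataset stores fractional rates).
#'
#' @param ds A [spectral_dataset()].
#' @param path Output/input file path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a [spectral_dataset()].
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- as.data.frame(ds$spectra)
  names(df) <- sprintf("wl_%.12g", ds$axis)
  df[[paste0("scaling_rate_", ds$response_unit)]] <- ds$responses
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param region Region label attached on read (not stored in the CSV).
#' @export
read_dataset_csv <- function(path, region = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  rate_col <- grep("^scaling_rate_", names(df))
  if (length(rate_col) != 1L) {
    stop("expected exactly one scaling_rate_* column in ", path,
         call. = FALSE)
  }
  unit <- sub("^scaling_rate_", "", names(df)[rate_col])
  axis <- as.numeric(sub("^wl_", "", names(df)[-rate_col]))
  spectral_dataset(axis, as.matrix(df[, -rate_col, drop = FALSE]),
                   df[[rate_col]], region,
                   response_unit = unit)
}
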