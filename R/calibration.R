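#' Scaling rate from pixel areas
#'
#' The scaling rate of a body region is the percentage of the region's
#' pixel area from which scales have been removed:
#' `P = 100 * P1 / P2`, with `P1` the scaled (descaled) pixel area and
#' `P2` the whole region's pixel area.
#'
#' @param p1 Scaled pixel area (pixel^2), `0 <= p1 <= p2`.
#' @param p2 Region pixel area (pixel^2), `> 0`.
#' @return An object of class `scaling_measurement`: list with `p1`, `p2`
#'   and the rate `p` in percent.
#' @examples
#' scaling_rate(50, 200)$p # 25
#' @export
scaling_rate <- function(p1, p2) {
  assert_scalar_number(p1, "p1", lower = 0)
  assert_scalar_number(p2, "p2")
  if (p2 <= 0) stop("`p2` (region pixel area) must be positive",
                    call. = FALSE)
  if (p1 > p2) stop("`p1` cannot exceed `p2`", call. = FALSE)
  structure(list(p1 = p1, p2 = p2, p = 100 * p1 / p2),
            class = "scaling_measurement")
}

#' Rectangular region of interest
#'
#' Pixel indices are 0-based and half-open (`row_start <= i < row_end`),
#' so the ROI height is simply `row_end - row_start` and adjacent ROIs
#' tile without overlap.
#'
#' @param row_start,row_end,col_start,col_end Integer pixel bounds.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(0, 2, 0, 2) # the top-left 2 x 2 block
#' @export
roi_spec <- function(row_start, row_end, col_start, col_end) {
  vals <- vapply(list(row_start, row_end, col_start, col_end), as.integer,
                 integer(1))
  if (anyNA(vals) || any(vals < 0L)) {
    stop("ROI bounds must be non-negative integers", call. = FALSE)
  }
  if (vals[1] >= vals[2] || vals[3] >= vals[4]) {
    stop("ROI is empty: need row_start < row_end and col_start < col_end",
         call. = FALSE)
  }
  structure(list(row_start = vals[1], row_end = vals[2],
                 col_start = vals[3], col_end = vals[4]),
            class = "roi_spec")
}

#' Reflectance correction against white and dark references
#'
#' Converts raw intensities to percent reflectance per pixel and band:
#' `R = 100 * (I_raw - I_dark) / (I_white - I_dark)`. This removes the
#' illumination profile and sensor dark current, and is invariant to any
#' common positive gain applied to all three frames.
#'
#' @param scene A `hypercube_scene` (see [simulate_cube()]), or any list
#'   with `cube`, `white_frame`, `dark_frame` arrays of equal dimension
#'   and an `axis`.
#' @return 3-D array of percent reflectance, with the wavelength axis
#'   attached as attribute `axis`.
#' @examples
#' sc <- simulate_cube(4, 4, 0.5, physics = scene_physics(0, 0, 0, seed = 1))
#' r <- correct_reflectance(sc)
#' range(r)
#' @export
correct_reflectance <- function(scene) {
  cube <- scene$cube; white <- scene$white_frame; dark <- scene$dark_frame
  stopifnot(is.array(cube), identical(dim(cube), dim(white)),
            identical(dim(cube), dim(dark)))
  denom <- white - dark
  if (any(denom <= 0)) {
    bad <- which(apply(denom <= 0, 3, any))
    lam <- if (!is.null(scene$axis)) sprintf(" (%.1f nm)", scene$axis[bad[1]])
           else ""
    stop(sprintf(
      "degenerate reference: white <= dark at band %d%s", bad[1], lam),
      call. = FALSE)
  }
  out <- 100 * (cube - dark) / denom
  attr(out, "axis") <- scene$axis
  out
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean of all pixel spectra inside the ROI — the
#' standard way a single calibration sample is extracted from a corrected
#' hyperspectral image.
#'
#' @param cube 3-D reflectance array (rows x cols x bands).
#' @param roi A [roi_spec()], 0-based half-open.
#' @return Numeric vector of length = band count.
#' @export
roi_mean_spectrum <- function(cube, roi) {
  stopifnot(is.array(cube), length(dim(cube)) == 3L,
            inherits(roi, "roi_spec"))
  d <- dim(cube)
  if (roi$row_end > d[1] || roi$col_end > d[2]) {
    stop("ROI exceeds cube bounds", call. = FALSE)
  }
  rows <- (roi$row_start + 1L):roi$row_end
  cols <- (roi$col_start + 1L):roi$col_end
  block <- cube[rows, cols, , drop = FALSE]
  apply(block, 3, mean)
}

#' Average replicate spectra
#'
#' Measurements taken in replicate (e.g. triplicate scans of the same
#' region) are combined by the arithmetic mean per band.
#'
#' @param spectra Matrix with one replicate per row, or list of equal
#'   length vectors.
#' @return Numeric mean spectrum.
#' @export
average_replicates <- function(spectra) {
  if (is.list(spectra)) spectra <- do.call(rbind, spectra)
  stopifnot(is.matrix(spectra), nrow(spectra) >= 1L)
  colMeans(spectra)
}

#' Trim a dataset to the analysis wavelength range
#'
#' Keeps the bands with `low_nm <= wavelength <= high_nm` (a small
#' numerical tolerance guards the boundaries). Short-wavelength camera
#' bands below 400 nm are noisy and overlapping, so the default analysis
#' range starts at 400 nm; on the default simulated axis this leaves
#' exactly 352 bands.
#'
#' @param ds A [spectral_dataset()].
#' @param low_nm,high_nm Analysis range bounds in nm.
#' @return The trimmed [spectral_dataset()].
#' @examples
#' ds <- simulate_dataset(5)
#' length(trim_to_analysis_range(ds)$axis) # 352
#' @export
trim_to_analysis_range <- function(ds, low_nm = 400, high_nm = 1024.7) {
  stopifnot(inherits(ds, "spectral_dataset"))
  assert_scalar_number(low_nm, "low_nm")
  assert_scalar_number(high_nm, "high_nm")
  tol <- 1e-8
  keep <- which(ds$axis >= low_nm - tol & ds$axis <= high_nm + tol)
  if (!length(keep)) {
    stop("no bands remain in [", low_nm, ", ", high_nm, "] nm",
         call. = FALSE)
  }
  ds_subset(ds, bands = keep)
}
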