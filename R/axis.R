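#' Wavelength axis
#'
#' A wavelength axis is a strictly increasing, uniformly spaced numeric
#' vector of band-centre wavelengths in nanometres. `wavelength_axis()`
#' validates a candidate vector; [default_wavelength_axis()] builds the axis
#' used throughout the package's simulations.
#'
#' @param values Numeric vector of wavelengths (nm).
#' @param spacing_tol Maximum permitted deviation from uniform spacing (nm).
#' @return The validated numeric vector, invisibly classed as before (plain
#'   numeric): axes are ordinary vectors so they compose with base
#'   subsetting.
#' @examples
#' ax <- wavelength_axis(seq(400, 700, by = 2))
#' length(ax)
#' @export
wavelength_axis <- function(values, spacing_tol = 1e-6) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values) ||
      any(!is.finite(values))) {
    stop("a wavelength axis needs at least one finite value", call. = FALSE)
  }
  if (length(values) == 1L) return(as.numeric(values))
  d <- diff(values)
  if (any(d <= 0)) {
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  }
  if (max(d) - min(d) > spacing_tol) {
    stop("wavelength axis must be uniformly spaced (within ", spacing_tol,
         " nm)", call. = FALSE)
  }
  as.numeric(values)
}

#' Default simulated wavelength axis
#'
#' The analysis range spans 400.6-1024.7 nm in 352 uniformly spaced bands
#' (spacing (1024.7 - 400.6)/351 nm, about 1.778 nm), matching the band
#' count that remains after trimming visible/NIR camera spectra at 400 nm.
#' The axis is extended downward by `n_pad` extra bands (to about 386 nm)
#' so that the trimming step has something to remove, emulating the
#' noisy short-wavelength margin of the sensor range (387.1 nm upward).
#'
#' @param n_pad Number of padding bands prepended below 400 nm (default 8).
#' @return Numeric wavelength vector of length `352 + n_pad`.
#' @examples
#' ax <- default_wavelength_axis()
#' range(ax)
#' sum(ax >= 400) # 352 analysis bands
#' @export
default_wavelength_axis <- function(n_pad = 8L) {
  n_pad <- as.integer(assert_scalar_number(n_pad, "n_pad", lower = 0))
  low <- 400.6
  high <- 1024.7
  n_analysis <- 352L
  sp <- (high - low) / (n_analysis - 1L)
  wavelength_axis(low + sp * seq.int(-n_pad, n_analysis - 1L))
}

assert_axis <- function(axis, min_bands = 2L, what = "axis") {
  axis <- wavelength_axis(axis)
  if (length(axis) < min_bands) {
    stop(sprintf("invalid %s: need at least %d bands, got %d",
                 what, min_bands, length(axis)), call. = FALSE)
  }
  axis
}
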