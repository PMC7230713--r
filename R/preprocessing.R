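#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: each band is replaced by the
#' value of a degree-`order` polynomial fitted to the `window` surrounding
#' bands. The default 7-point window with a cubic polynomial suppresses
#' high-frequency sensor noise while leaving any locally cubic signal
#' untouched (polynomials of degree <= `order` are reproduced exactly,
#' including at the spectrum ends, where the filter falls back to explicit
#' polynomial fits over the first/last window).
#'
#' @param spectrum Numeric vector.
#' @param window Odd window length (bands), default 7.
#' @param order Polynomial order, `< window`, default 3.
#' @return Smoothed vector of the same length.
#' @examples
#' x <- sin(seq(0, 4, length.out = 50)) + rnorm(50, 0, 0.05)
#' xs <- sg_smooth(x)
#' @export
sg_smooth <- function(spectrum, window = 7L, order = 3L) {
  stopifnot(is.numeric(spectrum))
  assert_scalar_number(window, "window", lower = 1)
  assert_scalar_number(order, "order", lower = 0)
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (order >= window) stop("`order` must be smaller than `window`",
                            call. = FALSE)
  if (length(spectrum) < window) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(spectrum, p = order, n = window))
}

#' First derivative of a spectrum
#'
#' Central-difference first derivative with respect to wavelength:
#' interior band `W` gets `(R[W+1] - R[W-1]) / (lambda[W+1] - lambda[W-1])`,
#' exact for locally quadratic spectra on a uniform axis. The two boundary
#' bands use one-sided differences so the band count is preserved.
#' Differentiation removes any additive baseline and turns broad
#' absorption shoulders into distinct peaks and valleys.
#'
#' @param spectrum Numeric vector (>= 3 bands).
#' @param axis Uniform wavelength axis of the same length (nm).
#' @return Derivative spectrum (reflectance units per nm), same length.
#' @examples
#' ax <- seq(400, 500, by = 2)
#' first_derivative(3 * ax + 1, ax)[2] # 3
#' @export
first_derivative <- function(spectrum, axis) {
  stopifnot(is.numeric(spectrum))
  if (length(spectrum) < 3L) {
    stop("first derivative needs at least 3 bands", call. = FALSE)
  }
  axis <- assert_axis(axis, min_bands = 3L)
  if (length(axis) != length(spectrum)) {
    stop("axis length must match spectrum length", call. = FALSE)
  }
  n <- length(spectrum)
  out <- numeric(n)
  out[2:(n - 1)] <- (spectrum[3:n] - spectrum[1:(n - 2)]) /
    (axis[3:n] - axis[1:(n - 2)])
  out[1] <- (spectrum[2] - spectrum[1]) / (axis[2] - axis[1])
  out[n] <- (spectrum[n] - spectrum[n - 1]) / (axis[n] - axis[n - 1])
  out
}

#' Multiplicative scatter correction
#'
#' Each sample spectrum is regressed by ordinary least squares on the
#' reference spectrum (the dataset mean): `X_i = m_i * ref + b_i + e`.
#' The corrected spectrum `(X_i - b_i) / m_i` has its sample-specific
#' multiplicative scatter and additive baseline removed, pulling every
#' spectrum onto the reference's scale.
#'
#' @param ds A [spectral_dataset()] with at least 2 samples.
#' @return List with `dataset` (the corrected [spectral_dataset()]) and
#'   `fit`, an object of class `msc_fit` holding the `reference` spectrum
#'   and per-sample `slopes` and `intercepts`.
#' @examples
#' ds <- simulate_dataset(20)
#' out <- msc_correct(ds)
#' range(out$fit$slopes)
#' @export
msc_correct <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  X <- ds$spectra
  if (nrow(X) < 2L) stop("MSC needs at least 2 samples", call. = FALSE)
  ref <- colMeans(X)
  vref <- stats::var(ref)
  if (!is.finite(vref) || vref <= .Machine$double.eps * max(abs(ref), 1)) {
    stop("degenerate reference: the mean spectrum has (near-)zero variance",
         call. = FALSE)
  }
  ref_c <- ref - mean(ref)
  # OLS slope of X_i on ref: cov(ref, X_i) / var(ref), via the centred ref
  slopes <- as.numeric(((X - rowMeans(X)) %*% ref_c) / sum(ref_c^2))
  intercepts <- rowMeans(X) - slopes * mean(ref)
  if (any(abs(slopes) < 1e-12)) {
    stop("degenerate sample: an MSC slope is numerically zero",
         call. = FALSE)
  }
  corrected <- (X - intercepts) / slopes
  fit <- structure(list(reference = ref, slopes = slopes,
                        intercepts = intercepts),
                   class = "msc_fit")
  list(dataset = ds_with_spectra(ds, corrected), fit = fit)
}

#' Apply a fitted MSC to new spectra
#'
#' Regresses each new spectrum on the stored training reference and
#' inverts the fitted affine distortion, so prediction-set samples are
#' corrected consistently with the calibration set.
#'
#' @param fit An `msc_fit` from [msc_correct()].
#' @param spectra Numeric matrix (samples x bands) or single spectrum.
#' @return Corrected matrix of the same shape.
#' @export
msc_apply <- function(fit, spectra) {
  stopifnot(inherits(fit, "msc_fit"))
  X <- if (is.matrix(spectra)) spectra else matrix(spectra, nrow = 1L)
  if (ncol(X) != length(fit$reference)) {
    stop("band count does not match the MSC reference", call. = FALSE)
  }
  ref <- fit$reference
  ref_c <- ref - mean(ref)
  slopes <- as.numeric(((X - rowMeans(X)) %*% ref_c) / sum(ref_c^2))
  intercepts <- rowMeans(X) - slopes * mean(ref)
  (X - intercepts) / slopes
}

#' Standard normal variate transform
#'
#' Row-oriented normalisation: the spectrum is centred to mean 0 and
#' scaled to unit sample standard deviation (denominator `m - 1` over the
#' `m` bands). Removes per-sample multiplicative scatter and offset
#' without using any other sample, and is invariant to positive affine
#' changes of the input.
#'
#' @param spectrum Numeric vector (>= 2 bands) with nonzero variance.
#' @return Transformed vector: mean 0, sample SD 1.
#' @examples
#' snv_transform(c(1, 2, 3)) # -1 0 1
#' @export
snv_transform <- function(spectrum) {
  stopifnot(is.numeric(spectrum))
  if (length(spectrum) < 2L) stop("SNV needs at least 2 bands",
                                  call. = FALSE)
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate spectrum: zero within-spectrum variance",
         call. = FALSE)
  }
  (spectrum - mean(spectrum)) / s
}

#' Apply a named pretreatment to a whole dataset
#'
#' Convenience dispatcher used by the model matrix: SG, FD and SNV operate
#' row-wise per sample; MSC is the one dataset-level fit (its reference is
#' the dataset mean spectrum).
#'
#' @param ds A [spectral_dataset()].
#' @param method One of `"SG"`, `"FD"`, `"MSC"`, `"SNV"`.
#' @param window,order Savitzky-Golay parameters (used for `"SG"`).
#' @return The pretreated [spectral_dataset()].
#' @export
preprocess_dataset <- function(ds, method = c("SG", "FD", "MSC", "SNV"),
                               window = 7L, order = 3L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  method <- match.arg(toupper(method), c("SG", "FD", "MSC", "SNV"))
  X <- ds$spectra
  out <- switch(
    method,
    SG = t(apply(X, 1, sg_smooth, window = window, order = order)),
    FD = t(apply(X, 1, first_derivative, axis = ds$axis)),
    SNV = t(apply(X, 1, snv_transform)),
    MSC = return(msc_correct(ds)$dataset)
  )
  ds_with_spectra(ds, out)
}
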