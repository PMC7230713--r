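#' Scene physics for the synthetic generator
#'
#' Collects the per-sample artifact magnitudes the generator injects and
#' that the spectral pretreatments are designed to remove: a multiplicative
#' scatter gain (what MSC/SNV correct), an additive baseline offset (what
#' the first derivative removes) and band-wise white noise (what
#' Savitzky-Golay smoothing suppresses).
#'
#' Defaults describe ROI-averaged, triplicate-averaged reflectance spectra:
#' sample-to-sample scatter and baseline shifts dominate (gain sd 0.1,
#' baseline sd 2 percent reflectance) while residual white noise is small
#' (0.1 percent reflectance), because spatial averaging over the thousands
#' of pixels in a 2 x 2 cm region of interest suppresses per-pixel sensor
#' noise by orders of magnitude.
#'
#' @param scatter_slope_sd Standard deviation of the multiplicative gain
#'   around 1 (unitless, >= 0).
#' @param baseline_sd Standard deviation of the additive baseline offset
#'   (percent reflectance, >= 0).
#' @param noise_sd Standard deviation of per-band white noise (percent
#'   reflectance, >= 0).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return An object of class `scene_physics`.
#' @examples
#' scene_physics()                       # study-condition defaults
#' scene_physics(0, 0, 0, seed = 7)      # artifact-free
#' @export
scene_physics <- function(scatter_slope_sd = 0.1, baseline_sd = 2,
                          noise_sd = 0.1, seed = 1L) {
  assert_scalar_number(scatter_slope_sd, "scatter_slope_sd", lower = 0)
  assert_scalar_number(baseline_sd, "baseline_sd", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(seed, "seed")
  structure(list(scatter_slope_sd = scatter_slope_sd,
                 baseline_sd = baseline_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_physics")
}

# gaussian absorption dip
dip <- function(axis, centre, width, depth) {
  depth * exp(-0.5 * ((axis - centre) / width)^2)
}

#' Generate a scale/skin endmember pair
#'
#' Builds smooth reflectance endmembers for fish scale and skin on a shared
#' wavelength axis. Scales reflect more than skin at every band (their
#' inorganic fibre structure scatters light, while the pigmented, moist
#' skin absorbs it), so `scale_spectrum >= skin_spectrum` everywhere and
#' the gap is strictly positive. Both curves carry absorption dips near
#' 420 nm (porphyrin Soret band), in the 500-600 nm window (myoglobin
#' bands, modelled at ~525 and ~575 nm) and near 960 nm (water overtone);
#' the dips are deeper in skin, which is what makes the scale-skin
#' difference wavelength-structured rather than a flat offset.
#'
#' @param axis Wavelength axis in nm (at least 10 bands).
#' @param seed Integer seed controlling the (small) random variation of
#'   dip centres, widths, depths and base level.
#' @return An object of class `endmember_pair`: list with
#'   `scale_spectrum`, `skin_spectrum` (unitless reflectance fractions in
#'   0-1) and `axis`.
#' @examples
#' em <- generate_endmembers(default_wavelength_axis(), seed = 1)
#' all(em$scale_spectrum > em$skin_spectrum)
#' @export
generate_endmembers <- function(axis, seed = 1L) {
  axis <- tryCatch(assert_axis(axis, min_bands = 10L),
                   error = function(e) stop("invalid axis: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  assert_scalar_number(seed, "seed")
  with_seed(seed, {
    base_shift <- stats::runif(1, -0.02, 0.02)
    centres <- c(420, 525, 575, 960) + stats::runif(4, -3, 3)
    widths <- c(8, 11, 11, 16) * stats::runif(4, 0.9, 1.1)
    skin_depths <- c(0.16, 0.09, 0.10, 0.11) * stats::runif(4, 0.85, 1.15)
    # scale dips are a strict fraction of the skin dips: the pigment,
    # myoglobin and water absorbers sit in the skin tissue, so the skin
    # curve is the more strongly absorbing one at every dip and the
    # scale-skin gap carries sharp wavelength structure
    scale_frac <- stats::runif(4, 0.20, 0.35)
  })
  r0 <- 0.30 + base_shift + 0.35 * stats::plogis((axis - 560) / 90)
  skin_dips <- rowSums(mapply(dip, centres, widths, skin_depths,
                              MoreArgs = list(axis = axis)))
  scale_dips <- rowSums(mapply(dip, centres, widths,
                               skin_depths * scale_frac,
                               MoreArgs = list(axis = axis)))
  skin <- 0.75 * r0 - skin_dips
  scale <- 1.05 * r0 + 0.02 - scale_dips
  skin <- pmin(pmax(skin, 0.02), 0.98)
  scale <- pmin(pmax(scale, 0.02), 0.98)
  structure(list(scale_spectrum = scale, skin_spectrum = skin, axis = axis),
            class = "endmember_pair")
}

# fractional-coverage linear mixture: rate in percent scaled (skin exposed)
mix_endmembers <- function(em, rate_percent) {
  p <- rate_percent / 100
  (1 - p) * em$scale_spectrum + p * em$skin_spectrum
}

check_rate_range <- function(rate_range) {
  if (!is.numeric(rate_range) || length(rate_range) != 2L ||
      anyNA(rate_range)) {
    stop("`rate_range` must be two finite numbers", call. = FALSE)
  }
  if (rate_range[1] > rate_range[2]) {
    stop("`rate_range` is empty (lower bound exceeds upper bound)",
         call. = FALSE)
  }
  if (rate_range[1] < 0 || rate_range[2] > 100) {
    stop("`rate_range` must lie within [0, 100] percent", call. = FALSE)
  }
  rate_range
}

#' Simulate a region dataset of ROI-mean spectra
#'
#' Draws `n` scaling rates uniformly over `rate_range` and produces, for
#' each, the ROI-mean reflectance spectrum of a surface whose area is
#' covered by scale and exposed skin in proportion to the rate. The
#' noise-free model is linear areal mixing,
#' `gain * ((1 - P/100) * scale + (P/100) * skin) + offset + noise`,
#' so reflectance decreases strictly and monotonically as the scaling rate
#' P grows. Gain, offset and noise magnitudes come from `physics`.
#'
#' @param n Number of samples (>= 2); the reference study design uses 100
#'   per body region.
#' @param axis Wavelength axis (nm).
#' @param physics A [scene_physics()] object (its seed drives both the
#'   endmember shapes and all random draws; fixed seed gives bit-identical
#'   datasets).
#' @param rate_range Two-element vector of scaling-rate bounds in percent,
#'   within \[0, 100\].
#' @param region Region label stored on the dataset.
#' @param endmembers Optional [generate_endmembers()] result; default
#'   derives the pair from `physics$seed` (use different seeds to emulate
#'   the distinct back/belly/tail spectral responses).
#' @param rate_scale Unit for the stored responses: `"percent"` (default,
#'   the convention of an area-ratio printed as %) or `"fraction"` (0-1;
#'   some published summary statistics use this scale).
#' @return A [spectral_dataset()] with reflectance in percent.
#' @examples
#' ds <- simulate_dataset(10, physics = scene_physics(seed = 3))
#' ds
#' @export
simulate_dataset <- function(n, axis = default_wavelength_axis(),
                             physics = scene_physics(),
                             rate_range = c(0, 100), region = "back",
                             endmembers = NULL,
                             rate_scale = c("percent", "fraction")) {
  assert_scalar_number(n, "n", lower = 2)
  n <- as.integer(n)
  axis <- assert_axis(axis, min_bands = 10L)
  stopifnot(inherits(physics, "scene_physics"))
  check_rate_range(rate_range)
  rate_scale <- match.arg(rate_scale)
  em <- endmembers %||% generate_endmembers(axis, physics$seed)
  stopifnot(inherits(em, "endmember_pair"),
            length(em$scale_spectrum) == length(axis))
  b <- length(axis)
  draws <- with_seed(physics$seed, {
    list(rates = stats::runif(n, rate_range[1], rate_range[2]),
         gains = 1 + stats::rnorm(n, 0, physics$scatter_slope_sd),
         offsets = stats::rnorm(n, 0, physics$baseline_sd),
         noise = matrix(stats::rnorm(n * b, 0, physics$noise_sd), n, b))
  })
  mix <- outer(1 - draws$rates / 100, em$scale_spectrum) +
    outer(draws$rates / 100, em$skin_spectrum)
  spectra <- draws$gains * (100 * mix) + draws$offsets + draws$noise
  responses <- if (rate_scale == "percent") draws$rates else draws$rates / 100
  spectral_dataset(axis, spectra, responses, region,
                   reflectance_unit = "percent", response_unit = rate_scale)
}

#' Simulate a hyperspectral scene with reference frames
#'
#' Builds a small hypercube of raw sensor intensities together with the
#' white and dark reference frames needed for reflectance correction, plus
#' the ground-truth scale mask. A fraction `coverage_fraction` of the
#' pixels (rounded to the nearest pixel count) carries the scale
#' endmember; the rest are exposed skin. Each pixel gets its own gain,
#' offset and noise draw from `physics`. Intensities are synthesised as
#' `dark + (white - dark) * reflectance`, so applying
#' [correct_reflectance()] recovers the simulated reflectance exactly.
#'
#' @param rows,cols Scene dimensions in pixels (product must be positive).
#' @param coverage_fraction Fraction of pixels still covered by scale, in
#'   \[0, 1\]. The region's scaling rate is `100 * (1 - coverage_fraction)`.
#' @param axis Wavelength axis (nm).
#' @param physics A [scene_physics()] object.
#' @param region Region label.
#' @return An object of class `hypercube_scene`: list with `cube`,
#'   `white_frame`, `dark_frame` (rows x cols x bands intensity arrays),
#'   logical `scale_mask` (rows x cols), `axis`, `region`.
#' @examples
#' sc <- simulate_cube(8, 8, 0.25, physics = scene_physics(seed = 2))
#' mean(sc$scale_mask)
#' @export
simulate_cube <- function(rows, cols, coverage_fraction,
                          axis = default_wavelength_axis(),
                          physics = scene_physics(), region = "back") {
  assert_scalar_number(rows, "rows", lower = 0)
  assert_scalar_number(cols, "cols", lower = 0)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols == 0L) stop("scene must contain at least one pixel",
                              call. = FALSE)
  assert_scalar_number(coverage_fraction, "coverage_fraction",
                       lower = 0, upper = 1)
  axis <- assert_axis(axis, min_bands = 10L)
  stopifnot(inherits(physics, "scene_physics"))
  em <- generate_endmembers(axis, physics$seed)
  npix <- rows * cols
  b <- length(axis)
  n_scale <- as.integer(round(coverage_fraction * npix))
  draws <- with_seed(physics$seed, {
    list(which_scale = if (n_scale > 0L) sample.int(npix, n_scale)
         else integer(0),
         gains = 1 + stats::rnorm(npix, 0, physics$scatter_slope_sd),
         offsets = stats::rnorm(npix, 0, physics$baseline_sd),
         noise = matrix(stats::rnorm(npix * b, 0, physics$noise_sd),
                        npix, b))
  })
  mask <- matrix(FALSE, rows, cols)
  mask[draws$which_scale] <- TRUE
  refl <- matrix(rep(em$skin_spectrum, each = npix), npix, b)
  if (n_scale > 0L) {
    refl[draws$which_scale, ] <-
      matrix(rep(em$scale_spectrum, each = n_scale), n_scale, b)
  }
  # per-pixel artifacts on the fractional reflectance scale
  refl <- draws$gains * refl + (draws$offsets + draws$noise) / 100
  # illumination profile of the white reference; dark current is flat
  white_level <- 3000 + 2000 * exp(-((axis - 700) / 250)^2)
  white <- array(rep(white_level, each = npix), dim = c(rows, cols, b))
  dark <- array(96, dim = c(rows, cols, b))
  cube <- dark + (white - dark) * array(refl, dim = c(rows, cols, b))
  structure(list(cube = cube, white_frame = white, dark_frame = dark,
                 scale_mask = mask, axis = axis, region = region),
            class = "hypercube_scene")
}

#' @export
print.hypercube_scene <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf(
    "<hypercube_scene> %d x %d pixels x %d bands, region '%s', scale coverage %.3f\n",
    d[1], d[2], d[3], x$region, mean(x$scale_mask)))
  invisible(x)
}
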