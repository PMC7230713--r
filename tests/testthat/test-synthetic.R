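test_that("default axis is uniform, covers the sensor range, trims to 352", {
  ax <- default_wavelength_axis()
  expect_length(ax, 360L)
  d <- diff(ax)
  expect_lt(max(d) - min(d), 1e-6)
  expect_lt(ax[1], 400)
  expect_equal(max(ax), 1024.7, tolerance = 1e-10)
  expect_identical(sum(ax >= 400), 352L)
})

test_that("axis validation rejects non-uniform or decreasing values", {
  expect_error(wavelength_axis(c(400, 410, 405)), "increasing")
  expect_error(wavelength_axis(c(400, 410, 425)), "uniform")
  expect_error(wavelength_axis(numeric(0)), "at least one")
  expect_equal(wavelength_axis(600), 600) # single band is degenerate-valid
})

test_that("endmembers satisfy ordering, dip and determinism invariants", {
  ax <- default_wavelength_axis()
  for (seed in 1:5) {
    em <- generate_endmembers(ax, seed)
    # scales reflect more than skin, strictly, at every band
    expect_true(min(em$scale_spectrum - em$skin_spectrum) > 0)
    expect_true(all(em$scale_spectrum <= 1 & em$skin_spectrum >= 0))
    # both curves show local absorption minima in the three windows
    for (spec in list(em$skin_spectrum, em$scale_spectrum)) {
      interior <- 2:(length(spec) - 1)
      mins <- interior[spec[interior] < spec[interior - 1] &
                         spec[interior] < spec[interior + 1]]
      for (win in list(c(410, 430), c(500, 600), c(950, 970))) {
        expect_true(any(ax[mins] >= win[1] & ax[mins] <= win[2]),
                    label = sprintf("local minimum in [%g,%g] nm, seed %d",
                                    win[1], win[2], seed))
      }
    }
  }
  expect_identical(generate_endmembers(ax, 3), generate_endmembers(ax, 3))
  expect_error(generate_endmembers(seq(400, 430, by = 5), 1),
               "invalid axis")
})

test_that("simulate_dataset mixes endmembers linearly in areal coverage", {
  ax <- default_wavelength_axis()
  em <- generate_endmembers(ax, 1)
  ph <- quiet_physics(seed = 1)
  ds0 <- simulate_dataset(3, ax, ph, rate_range = c(0, 0))
  ds100 <- simulate_dataset(3, ax, ph, rate_range = c(100, 100))
  expect_equal(ds0$spectra[1, ], 100 * em$scale_spectrum)
  expect_equal(ds100$spectra[2, ], 100 * em$skin_spectrum)
  # P = 50 with artifacts but no noise: gain * mean(endmembers) + offset
  ph2 <- scene_physics(0.2, 3, 0, seed = 9)
  ds50 <- simulate_dataset(4, ax, ph2, rate_range = c(50, 50),
                           endmembers = em)
  draws <- local({
    set.seed(9L)
    runif(4, 50, 50)
    g <- 1 + rnorm(4, 0, 0.2)
    o <- rnorm(4, 0, 3)
    list(g = g, o = o)
  })
  manual <- draws$g[3] * (100 * (em$scale_spectrum + em$skin_spectrum) / 2) +
    draws$o[3]
  expect_equal(ds50$spectra[3, ], manual, tolerance = 1e-12)
})

test_that("simulate_dataset enforces preconditions and determinism", {
  expect_error(simulate_dataset(1), "n")
  expect_error(simulate_dataset(5, rate_range = c(60, 40)), "empty")
  expect_error(simulate_dataset(5, rate_range = c(-5, 50)), "0, 100")
  a <- simulate_dataset(10, physics = scene_physics(seed = 42))
  b <- simulate_dataset(10, physics = scene_physics(seed = 42))
  expect_identical(a, b)
  ds <- simulate_dataset(100)
  expect_identical(dim(ds$spectra), c(100L, 360L))
  expect_true(all(ds$responses >= 0 & ds$responses <= 100))
  frac <- simulate_dataset(10, rate_scale = "fraction")
  expect_true(all(frac$responses <= 1))
})

test_that("noise-free spectra decrease strictly with the scaling rate", {
  ax <- default_wavelength_axis()
  ph <- quiet_physics(seed = 4)
  em <- generate_endmembers(ax, ph$seed)
  rates <- c(0, 20, 45, 80, 100)
  spectra <- vapply(rates, function(p) {
    simulate_dataset(2, ax, ph, rate_range = c(p, p))$spectra[1, ]
  }, numeric(length(ax)))
  for (j in seq_along(rates)[-1]) {
    expect_true(all(spectra[, j] < spectra[, j - 1]))
  }
})

test_that("simulate_cube honours coverage, references and determinism", {
  sc <- simulate_cube(20, 20, 0.25, physics = scene_physics(seed = 2))
  expect_lte(abs(sum(sc$scale_mask) - 100L), 1L)
  expect_identical(dim(sc$scale_mask), c(20L, 20L))
  expect_true(all(sc$white_frame > sc$dark_frame))
  sc0 <- simulate_cube(6, 5, 0, physics = scene_physics(seed = 2))
  expect_false(any(sc0$scale_mask))
  expect_error(simulate_cube(0, 5, 0.5), "at least one pixel")
  expect_error(simulate_cube(4, 4, 1.2), "coverage_fraction")
  a <- simulate_cube(5, 5, 0.5, physics = scene_physics(seed = 7))
  b <- simulate_cube(5, 5, 0.5, physics = scene_physics(seed = 7))
  expect_identical(a, b)
})

test_that("ROI mean of a noise-free cube matches the mixing formula", {
  ax <- default_wavelength_axis()
  cov <- 0.3
  sc <- simulate_cube(10, 10, cov, ax, quiet_physics(seed = 5))
  refl <- correct_reflectance(sc)
  roi <- roi_spec(0, 10, 0, 10)
  m <- roi_mean_spectrum(refl, roi)
  em <- generate_endmembers(ax, 5)
  p <- (1 - cov) * 100 # scaling rate implied by the coverage
  mixed <- 100 * ((1 - p / 100) * em$scale_spectrum +
                    (p / 100) * em$skin_spectrum)
  expect_equal(m, mixed, tolerance = 1e-9)
})

test_that("ENVI round trip and CSV round trip preserve data", {
  ax <- toy_axis(12)
  cube <- array(runif(4 * 3 * 12), dim = c(4, 3, 12))
  stem <- file.path(tempdir(), "toycube")
  write_envi_cube(cube, ax, stem)
  back <- read_envi_cube(stem)
  expect_equal(back$cube, cube, tolerance = 1e-6) # float32 storage
  expect_equal(back$axis, ax)
  ds <- simulate_dataset(8, physics = scene_physics(seed = 3))
  f <- file.path(tempdir(), "toyds.csv")
  write_dataset_csv(ds, f)
  ds2 <- read_dataset_csv(f, region = ds$region)
  expect_equal(ds2$spectra, ds$spectra, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(ds2$responses, ds$responses, tolerance = 1e-10)
})
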