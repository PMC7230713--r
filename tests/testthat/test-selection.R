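test_that("SPA finds the single informative band", {
  set.seed(20)
  n <- 30; b <- 15
  X <- matrix(rnorm(n * b), n, b)
  y <- 4 * X[, 7] + 2 # response is an exact function of band 7
  ds <- spectral_dataset(toy_axis(b), X, y)
  sub <- spa_select(ds, k_min = 1, k_max = 4)
  expect_true(7L %in% sub$indices)
  expect_lt(attr(sub, "rmse"), 1e-8)
})

test_that("SPA equals exhaustive search on a small instance", {
  set.seed(21)
  n <- 14; b <- 3
  X <- matrix(rnorm(n * b), n, b)
  y <- X %*% c(1, -2, 0.5) + rnorm(n, 0, 0.3)
  ds <- spectral_dataset(toy_axis(b), X, as.numeric(y))
  sub <- spa_select(ds, k_min = 1, k_max = 3)
  expect_equal(attr(sub, "rmse"), oracle_best_subset_rmse(X, y),
               tolerance = 1e-8)
})

test_that("SPA never selects a duplicated band twice", {
  set.seed(22)
  n <- 25; b <- 8
  X <- matrix(rnorm(n * b), n, b)
  X <- cbind(X, X[, 3]) # exact twin of band 3
  y <- as.numeric(X[, 1:8] %*% rnorm(8) + rnorm(n, 0, 0.2))
  ds <- spectral_dataset(toy_axis(9), X, y)
  sub <- spa_select(ds, k_min = 2, k_max = 6)
  expect_false(all(c(3L, 9L) %in% sub$indices))
})

test_that("SPA validates its size arguments", {
  ds <- spectral_dataset(toy_axis(5), matrix(rnorm(50), 10, 5), rnorm(10))
  expect_error(spa_select(ds, k_min = 4, k_max = 2), "k_min")
  expect_error(spa_select(ds, k_min = 1, k_max = 9), "band count")
})

test_that("RC selection targets the largest coefficient extrema", {
  set.seed(23)
  n <- 60; b <- 50
  ax <- toy_axis(b)
  X <- matrix(rnorm(n * b), n, b)
  # response loads on bands 10 and 35 only
  y <- as.numeric(3 * X[, 10] - 3 * X[, 35] + rnorm(n, 0, 0.1))
  ds <- spectral_dataset(ax, X, y)
  sub <- rc_select(ds, n_keep = 4)
  expect_true(all(c(10L, 35L) %in% sub$indices))
  expect_false(is.unsorted(sub$wavelengths_nm, strictly = TRUE))
})

test_that("RC returns every extremum (with a warning) when few exist", {
  ax <- toy_axis(30)
  set.seed(24)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- as.numeric(X[, 15] + rnorm(40, 0, 0.05))
  ds <- spectral_dataset(ax, X, y)
  beta <- attr(rc_select(ds, n_keep = 1, n_latent = 2), "beta")
  n_ext <- length(scalespec:::local_extrema(beta))
  expect_warning(sub <- rc_select(ds, n_keep = n_ext + 10, n_latent = 2),
                 "extrema")
  expect_length(sub$indices, n_ext)
  expect_false(is.unsorted(sub$indices, strictly = TRUE))
})

test_that("synchronous spectrum matches the direct two-sample formula", {
  ax <- toy_axis(6)
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(2, 1, 5, 3, 2, 8)
  ds <- spectral_dataset(ax, rbind(x1, x2), c(10, 90))
  sync <- synchronous_spectrum(ds)
  d <- (x1 - x2) / 2 # deviation of each sample from the mean spectrum
  manual <- (outer(d, d) + outer(-d, -d)) / (2 - 1)
  expect_equal(sync$matrix, manual, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("synchronous matrix is symmetric and positive semidefinite", {
  ds <- simulate_dataset(40, physics = scene_physics(seed = 6))
  sync <- synchronous_spectrum(ds)
  expect_lt(max(abs(sync$matrix - t(sync$matrix))), 1e-10)
  ev <- eigen(sync$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(diag(sync$matrix)))
  expect_true(all(diag(sync$matrix) >= 0))
  expect_false(is.unsorted(sync$perturbation))
  flat <- spectral_dataset(toy_axis(5), matrix(rnorm(15), 3, 5),
                           rep(50, 3))
  expect_error(synchronous_spectrum(flat), "distinct")
})

test_that("a single varying band produces a single auto-peak", {
  ax <- toy_axis(20)
  n <- 10
  rates <- seq(0, 100, length.out = n)
  X <- matrix(5, n, 20)
  X[, 12] <- 5 + rates * 0.1 # only band 12 responds to the perturbation
  ds <- spectral_dataset(ax, X, rates)
  sync <- synchronous_spectrum(ds)
  d <- diag(sync$matrix)
  expect_identical(which(d > 1e-10 * max(d)), 12L)
  sub <- autopeak_select(sync)
  expect_identical(sub$indices, 12L)
})

test_that("auto-peak selection ranks separated bumps by height", {
  ax <- toy_axis(120, from = 400, by = 5)
  centres <- c(430, 600, 750, 930)
  heights <- c(1, 0.6, 0.9, 0.3)
  diag_vals <- rowSums(vapply(seq_along(centres), function(i) {
    heights[i] * exp(-0.5 * ((ax - centres[i]) / 12)^2)
  }, numeric(120)))
  sync <- structure(list(matrix = diag(diag_vals), axis = ax,
                         perturbation = c(0, 100)),
                    class = "sync_spectrum")
  sub4 <- autopeak_select(sync, max_peaks = 8)
  expect_length(sub4$indices, 4L)
  expect_equal(sort(ax[sub4$indices]), sort(centres), tolerance = 2.5)
  sub2 <- autopeak_select(sync, max_peaks = 2)
  expect_equal(sort(ax[sub2$indices]),
               sort(centres[order(heights, decreasing = TRUE)][1:2]),
               tolerance = 2.5)
  flat <- structure(list(matrix = diag(rep(1, 10)), axis = toy_axis(10),
                         perturbation = c(0, 100)),
                    class = "sync_spectrum")
  expect_warning(empty <- autopeak_select(flat), "flat")
  expect_length(empty$indices, 0L)
})

test_that("all selectors are information-sufficient on ideal data", {
  ds <- simulate_dataset(100, physics = quiet_physics(seed = 30))
  ds <- trim_to_analysis_range(ds)
  split <- split_dataset(ds)
  cal <- scalespec:::ds_subset(ds, rows = split$calibration)
  Xp <- ds$spectra[split$prediction, , drop = FALSE]
  yp <- ds$responses[split$prediction]
  subsets <- list(
    spa = spa_select(cal, 1, 6),
    rc = rc_select(cal, 6, n_latent = 1), # noise-free mixing is rank 1
    cos = autopeak_select(synchronous_spectrum(cal))
  )
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]$indices
    lv <- 1L
    model <- fit_plsr(cal$spectra[, idx, drop = FALSE], cal$responses, lv)
    pred <- predict(model, Xp[, idx, drop = FALSE])
    r2 <- 100 * (1 - sum((yp - pred)^2) / sum((yp - mean(yp))^2))
    expect_gte(r2, 99)
  }
})

test_that("wavelength_subset enforces ordering and range", {
  ax <- toy_axis(10)
  expect_error(wavelength_subset(c(3, 3, 5), ax, "SPA"), "strictly")
  expect_error(wavelength_subset(c(0, 2), ax, "SPA"), "range")
  s <- wavelength_subset(c(2, 7), ax, "RC", "SNV")
  expect_equal(s$wavelengths_nm, ax[c(2, 7)])
  expect_length(s, 2L)
})
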