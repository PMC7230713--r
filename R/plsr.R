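#' Split a dataset into calibration and prediction sets
#'
#' The default `"rank"` strategy sorts samples by response and assigns
#' prediction samples at evenly spaced ranks (the positions where
#' `floor(i * n_pred / n)` increments), so both sets span the full
#' response range — at the reference design of 100 samples split 60/40
#' this picks 2 prediction samples out of every 5 consecutive ranks. The
#' `"random"` strategy draws the prediction set uniformly, reproducibly
#' under `seed`.
#'
#' @param ds A [spectral_dataset()].
#' @param n_cal,n_pred Calibration / prediction sizes; must sum to the
#'   sample count (defaults 60/40).
#' @param strategy `"rank"` (deterministic, default) or `"random"`.
#' @param seed Seed for the random strategy.
#' @return An object of class `split_spec`: list with integer
#'   `calibration` and `prediction` index vectors, `strategy`, `seed`.
#' @examples
#' ds <- simulate_dataset(100)
#' sp <- split_dataset(ds)
#' lengths(sp[c("calibration", "prediction")])
#' @export
split_dataset <- function(ds, n_cal = 60L, n_pred = 40L,
                          strategy = c("rank", "random"), seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  strategy <- match.arg(strategy)
  n <- nrow(ds$spectra)
  n_cal <- as.integer(n_cal); n_pred <- as.integer(n_pred)
  if (n_cal < 1L || n_pred < 1L || n_cal + n_pred != n) {
    stop(sprintf("n_cal + n_pred must equal the sample count (%d)", n),
         call. = FALSE)
  }
  if (strategy == "rank") {
    ord <- order(ds$responses, seq_len(n))
    i <- seq_len(n)
    is_pred <- (i * n_pred) %/% n > ((i - 1L) * n_pred) %/% n
    pred <- sort(ord[is_pred])
  } else {
    pred <- sort(with_seed(seed, sample.int(n, n_pred)))
  }
  structure(list(calibration = setdiff(seq_len(n), pred),
                 prediction = pred, strategy = strategy,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Fit a single-response PLSR model (NIPALS)
#'
#' Iterative latent-variable decomposition of the centred calibration
#' data: each component's weight vector is the covariance direction
#' between the deflated predictors and the response, giving mutually
#' orthogonal score vectors. Weights, loadings and the response loadings
#' are folded into a single regression-coefficient vector `beta` and
#' `intercept` so prediction is one matrix product. No unit-variance
#' scaling is applied to the predictors — the spectral pretreatments are
#' expected to have conditioned them already.
#'
#' @param X Calibration spectra matrix (samples x bands).
#' @param y Calibration responses (scaling rate, percent).
#' @param n_latent Number of latent variables,
#'   `<= min(n_samples - 1, band count)`.
#' @return An object of class `plsr_model` with fields `n_latent`,
#'   `x_mean`, `y_mean`, `weights`, `x_loadings`, `y_loadings`, `scores`,
#'   `beta`, `intercept`.
#' @examples
#' ds <- simulate_dataset(30)
#' m <- fit_plsr(ds$spectra, ds$responses, n_latent = 3)
#' m$n_latent
#' @export
fit_plsr <- function(X, y, n_latent) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); b <- ncol(X)
  if (length(y) != n) stop("X and y sizes disagree", call. = FALSE)
  assert_scalar_number(n_latent, "n_latent", lower = 1)
  n_latent <- as.integer(n_latent)
  if (n_latent > min(n - 1L, b)) {
    stop(sprintf("n_latent must be <= min(n_samples - 1, bands) = %d",
                 min(n - 1L, b)), call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean)
  f <- y - y_mean
  tot_var <- sum(E^2)
  W <- matrix(0, b, n_latent)
  P <- matrix(0, b, n_latent)
  Tm <- matrix(0, n, n_latent)
  q <- numeric(n_latent)
  tol <- 1e-12 * max(tot_var, 1)
  for (a in seq_len(n_latent)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 <= tol * max(sum(f^2), .Machine$double.eps)) {
      stop(sprintf(
        "rank deficiency: only %d latent variable(s) achievable", a - 1L),
        call. = FALSE)
    }
    w <- w / nw
    t_a <- E %*% w
    tt <- sum(t_a^2)
    if (tt <= tol) {
      stop(sprintf(
        "rank deficiency: only %d latent variable(s) achievable", a - 1L),
        call. = FALSE)
    }
    p_a <- crossprod(E, t_a) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - t_a %*% t(p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  # direct-prediction coefficients: beta = W (P'W)^{-1} q
  beta <- as.numeric(W %*% solve(crossprod(P, W), q))
  structure(list(n_latent = n_latent, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q, scores = Tm,
                 beta = beta, intercept = y_mean - sum(x_mean * beta)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s), %d bands\n",
              x$n_latent, length(x$beta)))
  invisible(x)
}

#' Predict scaling rates from a fitted PLSR model
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix (samples x bands) or single spectrum with the
#'   model's band count.
#' @param ... Unused.
#' @return Numeric vector of predicted scaling rates.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  if (ncol(X) != length(object$beta)) {
    stop(sprintf("band count mismatch: model has %d bands, newdata %d",
                 length(object$beta), ncol(X)), call. = FALSE)
  }
  as.numeric(X %*% object$beta + object$intercept)
}

# all nested coefficient vectors beta_k (k = 1..A) from one NIPALS fit
plsr_beta_path <- function(model) {
  A <- model$n_latent
  vapply(seq_len(A), function(k) {
    W <- model$weights[, seq_len(k), drop = FALSE]
    P <- model$x_loadings[, seq_len(k), drop = FALSE]
    as.numeric(W %*% solve(crossprod(P, W), model$y_loadings[seq_len(k)]))
  }, numeric(length(model$x_mean)))
}

#' Choose the number of latent variables by cross-validation
#'
#' K-fold cross-validated RMSE is computed for each candidate component
#' count (folds are assigned deterministically across the response ranks,
#' so every fold spans the rate range). The returned count is the
#' smallest one whose CV RMSE is within one standard error of the
#' minimum — the parsimony rule that keeps noise-chasing components out.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param max_lv Largest component count to try (default
#'   `min(20, n - max fold size - 1, bands)`).
#' @param folds Number of folds (default 10), `<= n`.
#' @return Integer component count.
#' @export
select_latent_variables <- function(X, y, max_lv = NULL, folds = 10L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  fold_of <- integer(n)
  fold_of[order(y, seq_len(n))] <- rep_len(seq_len(folds), n)
  min_train <- n - max(tabulate(fold_of, folds)) # smallest training size
  cap <- min(20L, min_train - 1L, ncol(X))
  max_lv <- as.integer(max_lv %||% cap)
  if (max_lv < 1L) stop("max_lv must be >= 1", call. = FALSE)
  max_lv <- min(max_lv, cap)
  if (max_lv == 1L) return(1L)
  rmse <- matrix(NA_real_, folds, max_lv)
  achieved <- max_lv
  for (k in seq_len(folds)) {
    hold <- which(fold_of == k)
    fit <- NULL
    a_try <- achieved
    while (is.null(fit) && a_try >= 1L) {
      fit <- tryCatch(fit_plsr(X[-hold, , drop = FALSE], y[-hold], a_try),
                      error = function(e) NULL)
      if (is.null(fit)) a_try <- a_try - 1L
    }
    if (is.null(fit)) stop("PLSR rank deficiency in every fold",
                           call. = FALSE)
    achieved <- min(achieved, a_try)
    betas <- plsr_beta_path(fit)
    Xh <- sweep(X[hold, , drop = FALSE], 2L, fit$x_mean)
    pred <- Xh %*% betas + fit$y_mean # n_hold x a_try
    rmse[k, seq_len(a_try)] <-
      sqrt(colMeans((pred - y[hold])^2))
  }
  rmse <- rmse[, seq_len(achieved), drop = FALSE]
  cv_mean <- colMeans(rmse)
  k_min <- which.min(cv_mean)
  se <- stats::sd(rmse[, k_min]) / sqrt(folds)
  as.integer(which(cv_mean <= cv_mean[k_min] + se)[1L])
}
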