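#' Characteristic-wavelength subset
#'
#' An ordered set of selected band indices with the wavelengths they map
#' to and the provenance (selection method, pretreatment). Indices are
#' strictly increasing and unique. An empty subset is only produced by
#' [autopeak_select()] on a featureless diagonal, and is flagged by a
#' warning there.
#'
#' @param indices Integer band positions (1-based, strictly increasing).
#' @param axis Wavelength axis of the parent dataset.
#' @param method Selection method label (`"SPA"`, `"RC"`, `"2D-COS"`,
#'   `"FW"`).
#' @param pretreatment Optional pretreatment label (`"SG"`, `"FD"`,
#'   `"MSC"`, `"SNV"`).
#' @return An object of class `wavelength_subset`.
#' @export
wavelength_subset <- function(indices, axis, method,
                              pretreatment = NA_character_) {
  axis <- assert_axis(axis)
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L) || any(indices > length(axis))) {
    stop("subset indices out of band range", call. = FALSE)
  }
  if (is.unsorted(indices, strictly = TRUE)) {
    stop("subset indices must be strictly increasing and unique",
         call. = FALSE)
  }
  structure(list(indices = indices, wavelengths_nm = axis[indices],
                 method = as.character(method)[1L],
                 pretreatment = as.character(pretreatment)[1L]),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat(sprintf("<wavelength_subset> %s%s: %d band(s)\n", x$method,
              if (is.na(x$pretreatment)) "" else paste0("/", x$pretreatment),
              length(x$indices)))
  if (length(x$indices)) {
    cat("  ", paste(sprintf("%.1f", x$wavelengths_nm), collapse = ", "),
        " nm\n", sep = "")
  }
  invisible(x)
}

#' @export
length.wavelength_subset <- function(x) length(x$indices)

# leave-one-out RMSE of multiple linear regression of y on X[, idx]
loo_rmse_mlr <- function(X, y, idx) {
  Xd <- cbind(1, X[, idx, drop = FALSE])
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) return(Inf)
  Q <- qr.Q(qr_x)
  h <- rowSums(Q^2)
  e <- qr.resid(qr_x, y)
  if (any(1 - h < 1e-10)) return(Inf)
  sqrt(mean((e / (1 - h))^2))
}

# leave-one-out RMSE of a k-component PLSR on X[, idx]
loo_rmse_plsr <- function(X, y, idx) {
  n <- nrow(X)
  k <- min(length(idx), n - 2L)
  pred <- vapply(seq_len(n), function(i) {
    fit <- tryCatch(fit_plsr(X[-i, idx, drop = FALSE], y[-i], k),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    predict(fit, X[i, idx, drop = FALSE])
  }, numeric(1))
  if (anyNA(pred)) return(Inf)
  sqrt(mean((pred - y)^2))
}

#' Successive projections algorithm
#'
#' Forward selection of minimally collinear bands. From every candidate
#' start band a chain is grown: at each step all remaining band vectors
#' are projected onto the orthogonal complement of the bands already
#' chosen, and the band with the largest remaining projection norm is
#' appended — so each new band carries the most information not already
#' present. Every chain prefix of length `k_min..k_max` is scored by the
#' leave-one-out RMSE of an internal regression on those bands, and the
#' returned subset is the smallest one whose RMSE is within `tol`
#' (relative) of the global minimum.
#'
#' @param ds Calibration [spectral_dataset()].
#' @param k_min,k_max Candidate subset sizes (defaults 3 and 10,
#'   reflecting the 3-9 characteristic wavelengths typical of published
#'   scaling-rate models).
#' @param scorer Internal regression for the RMSE score: `"mlr"`
#'   (multiple linear regression, the standard SPA companion; default) or
#'   `"plsr"`.
#' @param tol Relative RMSE tolerance defining "minimum" (default 0.01).
#' @return A [wavelength_subset()] with method `"SPA"`. The achieved LOO
#'   RMSE is attached as attribute `rmse`.
#' @export
spa_select <- function(ds, k_min = 3L, k_max = 10L,
                       scorer = c("mlr", "plsr"), tol = 0.01) {
  stopifnot(inherits(ds, "spectral_dataset"))
  scorer <- match.arg(scorer)
  X <- ds$spectra
  y <- ds$responses
  n <- nrow(X); b <- ncol(X)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_min > k_max) {
    stop("need 1 <= k_min <= k_max", call. = FALSE)
  }
  if (k_max > b) stop("k_max exceeds the band count", call. = FALSE)
  k_max <- min(k_max, n - 3L)
  if (k_max < k_min) stop("too few samples for the requested subset sizes",
                          call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  norms0 <- colSums(Xc^2)
  if (max(norms0) <= 1e-12) {
    stop("degenerate dataset: all centred band norms vanish", call. = FALSE)
  }
  score_fun <- if (scorer == "mlr") loo_rmse_mlr else loo_rmse_plsr
  drop_tol <- 1e-10 * max(norms0)
  best <- list(rmse = Inf, k = NA_integer_, idx = NULL)
  results <- vector("list", 0L)
  for (start in seq_len(b)) {
    P <- Xc
    sel <- integer(0)
    cur <- start
    for (j in seq_len(k_max)) {
      sel <- c(sel, cur)
      u <- P[, cur]
      uu <- sum(u^2)
      if (uu <= drop_tol) break
      P <- P - u %*% (crossprod(u, P) / uu)
      if (j == k_max) break
      nrm <- colSums(P^2)
      nrm[sel] <- -Inf
      if (max(nrm) <= drop_tol) break # nothing independent left
      cur <- which.max(nrm)
    }
    for (k in k_min:min(k_max, length(sel))) {
      r <- score_fun(X, y, sel[seq_len(k)])
      results[[length(results) + 1L]] <-
        list(rmse = r, k = k, idx = sel[seq_len(k)])
    }
  }
  if (!length(results)) {
    stop("degenerate dataset: no SPA chain reached the requested size",
         call. = FALSE)
  }
  rmses <- vapply(results, `[[`, numeric(1), "rmse")
  ks <- vapply(results, `[[`, integer(1), "k")
  gmin <- min(rmses)
  if (!is.finite(gmin)) {
    stop("degenerate dataset: every candidate subset is rank deficient",
         call. = FALSE)
  }
  ok <- rmses <= gmin * (1 + tol)
  k_star <- min(ks[ok])
  pick <- which(ok & ks == k_star)
  pick <- pick[which.min(rmses[pick])]
  out <- wavelength_subset(sort(results[[pick]]$idx), ds$axis, "SPA")
  attr(out, "rmse") <- rmses[pick]
  out
}

#' Regression-coefficient wavelength selection
#'
#' Fits a full-spectrum PLSR model and selects the bands at the local
#' extrema (peaks and valleys) of the regression-coefficient vector with
#' the largest absolute values — the bands that drive the full model
#' hardest.
#'
#' @param ds Calibration [spectral_dataset()].
#' @param n_keep Number of extrema to keep (default 8; published subsets
#'   of this kind contain 4-9 bands). If fewer extrema exist, all are
#'   returned with a warning.
#' @param n_latent Latent-variable count for the full-spectrum fit;
#'   default chosen by [select_latent_variables()].
#' @return A [wavelength_subset()] with method `"RC"`; the full
#'   coefficient vector is attached as attribute `beta`.
#' @export
rc_select <- function(ds, n_keep = 8L, n_latent = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n_keep <- as.integer(n_keep)
  if (n_keep < 1L) stop("n_keep must be >= 1", call. = FALSE)
  X <- ds$spectra; y <- ds$responses
  lv <- n_latent %||% select_latent_variables(X, y)
  model <- fit_plsr(X, y, lv)
  beta <- model$beta
  ext <- local_extrema(beta)
  if (!length(ext)) ext <- which.max(abs(beta))
  if (length(ext) < n_keep) {
    warning(sprintf(
      "only %d regression-coefficient extrema available (requested %d)",
      length(ext), n_keep))
    keep <- ext
  } else {
    keep <- ext[order(abs(beta[ext]), decreasing = TRUE)][seq_len(n_keep)]
  }
  out <- wavelength_subset(sort(keep), ds$axis, "RC")
  attr(out, "beta") <- beta
  out
}

# interior indices where the sequence turns (strict peaks and valleys)
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  d <- diff(v)
  s <- sign(d)
  # carry the last nonzero slope through plateaus
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  which(s[-1] * s[-(n - 1L)] < 0) + 1L
}

#' Synchronous two-dimensional correlation spectrum
#'
#' Orders the samples by the external perturbation (the scaling rate),
#' forms the dynamic spectra as deviations from the perturbation-mean
#' spectrum, and returns the synchronous correlation matrix
#' `t(dynamic) %*% dynamic / (m - 1)`. Its diagonal auto-peaks mark the
#' bands whose intensity responds most strongly to the perturbation.
#'
#' @param ds A [spectral_dataset()] with at least 2 distinct scaling
#'   rates.
#' @return An object of class `sync_spectrum`: list with the symmetric
#'   positive semidefinite `matrix`, the `axis`, and `perturbation` (the
#'   sorted scaling rates).
#' @export
synchronous_spectrum <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  y <- ds$responses
  m <- length(y)
  if (m < 2L || length(unique(y)) < 2L) {
    stop("need at least 2 samples with distinct scaling rates",
         call. = FALSE)
  }
  ord <- order(y, seq_len(m))
  dyn <- sweep(ds$spectra[ord, , drop = FALSE], 2L,
               colMeans(ds$spectra))
  M <- crossprod(dyn) / (m - 1)
  M <- (M + t(M)) / 2 # enforce exact symmetry against rounding
  structure(list(matrix = M, axis = ds$axis, perturbation = y[ord]),
            class = "sync_spectrum")
}

#' @export
print.sync_spectrum <- function(x, ...) {
  cat(sprintf(
    "<sync_spectrum> %d x %d bands, %d perturbation levels\n",
    nrow(x$matrix), ncol(x$matrix), length(x$perturbation)))
  invisible(x)
}

#' Write the synchronous matrix as CSV (for external plotting)
#'
#' @param sync A `sync_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync_csv <- function(sync, path) {
  stopifnot(inherits(sync, "sync_spectrum"))
  m <- sync$matrix
  dimnames(m) <- list(sprintf("%.6g", sync$axis), sprintf("%.6g", sync$axis))
  utils::write.csv(m, path)
  invisible(path)
}

# prominence of a local maximum: height minus the higher of the two key
# saddles (minimum on the walk toward higher terrain on each side)
peak_prominence <- function(d, peaks) {
  vapply(peaks, function(p) {
    h <- d[p]
    left <- if (p > 1L) {
      seg <- d[(p - 1L):1L]
      stop_at <- which(seg > h)[1L]
      min(seg[seq_len(if (is.na(stop_at)) length(seg) else stop_at)])
    } else h
    right <- if (p < length(d)) {
      seg <- d[(p + 1L):length(d)]
      stop_at <- which(seg > h)[1L]
      min(seg[seq_len(if (is.na(stop_at)) length(seg) else stop_at)])
    } else h
    h - max(left, right)
  }, numeric(1))
}

#' Auto-peak wavelength selection from a synchronous spectrum
#'
#' Finds the local maxima of the synchronous matrix diagonal whose
#' prominence exceeds `prominence * max(diagonal)`, keeps the tallest
#' `max_peaks` of them, and returns the corresponding bands (sorted by
#' wavelength). Boundary bands count as peaks when they rise above their
#' single neighbour, since perturbation-sensitive bands can sit at the
#' edge of the analysis range.
#'
#' @param sync A [synchronous_spectrum()] result.
#' @param max_peaks Cap on the number of characteristic wavelengths
#'   (default 8; synchronous-map selections typically yield 3-8).
#' @param prominence Prominence threshold as a fraction of the diagonal
#'   maximum (default 0.05), separating weak but real auto-peaks from
#'   ripple.
#' @return A [wavelength_subset()] with method `"2D-COS"`; empty (with a
#'   warning) if the diagonal is flat.
#' @export
autopeak_select <- function(sync, max_peaks = 8L, prominence = 0.05) {
  stopifnot(inherits(sync, "sync_spectrum"))
  max_peaks <- as.integer(max_peaks)
  if (max_peaks < 1L) stop("max_peaks must be >= 1", call. = FALSE)
  d <- diag(sync$matrix)
  n <- length(d)
  rng <- max(d) - min(d)
  if (max(d) <= 0 || rng <= 1e-12 * max(abs(d), 1)) {
    warning("flat synchronous diagonal: no auto-peaks found")
    out <- structure(list(indices = integer(0), wavelengths_nm = numeric(0),
                          method = "2D-COS", pretreatment = NA_character_),
                     class = "wavelength_subset")
    return(out)
  }
  interior <- which(d[2:(n - 1)] >= d[1:(n - 2)] &
                      d[2:(n - 1)] > d[3:n]) + 1L
  edges <- c(if (d[1] > d[2]) 1L, if (d[n] > d[n - 1L]) n)
  peaks <- sort(unique(c(interior, edges)))
  prom <- peak_prominence(d, peaks)
  peaks <- peaks[prom >= prominence * max(d)]
  if (!length(peaks)) {
    warning("no auto-peak exceeds the prominence threshold")
    out <- structure(list(indices = integer(0), wavelengths_nm = numeric(0),
                          method = "2D-COS", pretreatment = NA_character_),
                     class = "wavelength_subset")
    return(out)
  }
  keep <- peaks[order(d[peaks], decreasing = TRUE)]
  keep <- keep[seq_len(min(max_peaks, length(keep)))]
  wavelength_subset(sort(keep), sync$axis, "2D-COS")
}
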