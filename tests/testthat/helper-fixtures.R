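# shared fixtures, built in code at test time

quiet_physics <- function(seed = 1L) scene_physics(0, 0, 0, seed = seed)

# small uniform axis for fast unit tests
toy_axis <- function(n = 40L, from = 400, by = 5) {
  seq(from, by = by, length.out = n)
}

# leave-one-out RMSE of MLR with intercept: independent oracle used by the
# SPA tests (kept deliberately naive — one lm per left-out sample)
oracle_loo_rmse <- function(X, y, idx) {
  n <- nrow(X)
  Xd <- cbind(1, X[, idx, drop = FALSE])
  pred <- vapply(seq_len(n), function(i) {
    # explicit refit without sample i (no hat-matrix shortcut)
    cf <- tryCatch(qr.solve(Xd[-i, , drop = FALSE], y[-i]),
                   error = function(e) rep(NA_real_, ncol(Xd)))
    sum(cf * Xd[i, ])
  }, numeric(1))
  if (anyNA(pred)) return(Inf)
  sqrt(mean((pred - y)^2))
}

# exhaustive search over all non-empty band subsets by the same criterion
oracle_best_subset_rmse <- function(X, y) {
  b <- ncol(X)
  best <- Inf
  for (k in seq_len(b)) {
    combos <- utils::combn(b, k)
    for (j in seq_len(ncol(combos))) {
      r <- oracle_loo_rmse(X, y, combos[, j])
      if (r < best) best <- r
    }
  }
  best
}
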