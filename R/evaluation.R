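#' Calibration / prediction metrics
#'
#' The standard chemometric evaluation quantities for a fitted model on
#' one sample set:
#' * `r2` — coefficient of determination, in percent:
#'   `100 * (1 - SS_res / SS_tot)`;
#' * `rmse` — root mean square error, in the response unit (percent
#'   scaling rate);
#' * `sd` — sample standard deviation of the *predicted* values, reported
#'   on the fractional scale (percent / 100), the convention used in
#'   published evaluation tables where e.g. 0.18 means 18%;
#' * `se` — `sd / sqrt(n)`;
#' * `rpd` — relative percent deviation, `100 * sd / rmse` (i.e. the
#'   prediction SD in percent over RMSEP), reported for the prediction
#'   set.
#'
#' @param y_true Observed scaling rates (percent).
#' @param y_pred Predicted scaling rates (percent).
#' @param set_label `"calibration"` or `"prediction"`; RPD is only
#'   meaningful (and only returned non-`NA`) for the prediction set.
#' @return List with `set`, `n`, `r2`, `rmse`, `sd`, `se`, `rpd`.
#' @examples
#' compute_metrics(c(0, 50, 100), c(1, 49, 99), "prediction")$r2
#' @export
compute_metrics <- function(y_true, y_pred,
                            set_label = c("calibration", "prediction")) {
  set_label <- match.arg(set_label)
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  n <- length(y_true)
  if (n != length(y_pred) || n < 2L) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) {
    stop("zero response variance: R^2 is undefined", call. = FALSE)
  }
  ss_res <- sum((y_true - y_pred)^2)
  rmse <- sqrt(mean((y_true - y_pred)^2))
  sd_frac <- stats::sd(y_pred) / 100
  list(set = set_label, n = n,
       r2 = 100 * (1 - ss_res / ss_tot),
       rmse = rmse,
       sd = sd_frac,
       se = sd_frac / sqrt(n),
       rpd = if (set_label == "prediction") rpd(sd_frac, rmse) else NA_real_)
}

#' Relative percent deviation
#'
#' `RPD = 100 * SD_pred / RMSEP`, where `SD_pred` is the standard
#' deviation of the predicted values on the fractional scale and RMSEP is
#' in percent — equivalently, prediction-set SD over RMSEP on a common
#' scale. Values above 2 mark excellent predictive ability.
#'
#' @param sd_pred Prediction-set SD on the fractional scale (e.g. 0.18).
#' @param rmsep RMSEP in percent (e.g. 1.43).
#' @return The RPD value.
#' @examples
#' rpd(0.18, 1.43) # about 12.59
#' @export
rpd <- function(sd_pred, rmsep) {
  assert_scalar_number(sd_pred, "sd_pred", lower = 0)
  assert_scalar_number(rmsep, "rmsep")
  if (rmsep <= 0) stop("`rmsep` must be positive", call. = FALSE)
  100 * sd_pred / rmsep
}

#' Grade a model's predictive performance
#'
#' Applies the conventional chemometric thresholds. Fit grade from the
#' prediction-set R2 (percent): below 82 `"inaccurate"`, 82 to 90
#' (inclusive) `"good"`, above 90 `"excellent"`. RPD grade: below 1.5
#' `"unusable"`, 1.5 to 2 (inclusive) `"usable"`, above 2 `"excellent"`.
#' Both boundaries belong to the middle class ("between" is read as the
#' closed interval).
#'
#' @param report A list or one-row data frame with `r2_pred` (or
#'   `R2P_pct`) and `rpd` (or `RPD`).
#' @return List with `fit_grade` and `rpd_grade`.
#' @examples
#' grade_model(list(r2_pred = 95.55, rpd = 3.98))
#' @export
grade_model <- function(report) {
  r2p <- report$r2_pred %||% report$R2P_pct
  rp <- report$rpd %||% report$RPD
  if (is.null(r2p) || is.null(rp) || !is.finite(r2p) || !is.finite(rp)) {
    stop("report must contain finite r2_pred and rpd", call. = FALSE)
  }
  list(
    fit_grade = if (r2p < 82) "inaccurate" else if (r2p <= 90) "good"
                else "excellent",
    rpd_grade = if (rp < 1.5) "unusable" else if (rp <= 2) "usable"
                else "excellent"
  )
}

#' Configuration for the model matrix
#'
#' Bundles every knob of the pretreatment x wavelength-selection model
#' matrix so a full run is reproducible from one object.
#'
#' @param pretreatments Pretreatments to run (default all four).
#' @param selectors Wavelength sets to run: `"FW"` (full wavelengths) and
#'   the three characteristic-wavelength selectors.
#' @param n_cal,n_pred Split sizes (default 60/40).
#' @param split_strategy,split_seed See [split_dataset()].
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param spa_k_min,spa_k_max SPA subset-size range.
#' @param rc_n_keep RC extrema count.
#' @param cos_max_peaks,cos_prominence Auto-peak selection parameters.
#' @param max_lv Cap on PLSR latent variables (default 20).
#' @param cv_folds Cross-validation folds for component selection.
#' @return A list of class `model_matrix_config`.
#' @export
model_matrix_config <- function(pretreatments = c("SG", "FD", "MSC", "SNV"),
                                selectors = c("FW", "SPA", "RC", "2D-COS"),
                                n_cal = 60L, n_pred = 40L,
                                split_strategy = "rank", split_seed = 1L,
                                sg_window = 7L, sg_order = 3L,
                                spa_k_min = 3L, spa_k_max = 10L,
                                rc_n_keep = 8L,
                                cos_max_peaks = 8L, cos_prominence = 0.05,
                                max_lv = 20L, cv_folds = 10L) {
  structure(as.list(environment()), class = "model_matrix_config")
}

#' Run the pretreatment x wavelength-selection model matrix
#'
#' For each pretreatment the dataset is transformed as a whole (the MSC
#' reference is the dataset mean), split into calibration and prediction
#' sets, and evaluated with the full wavelengths and with each
#' characteristic-wavelength selector applied to the calibration set. A
#' PLSR model with a cross-validated component count is fitted per cell,
#' giving (by default) the 4 x 4 = 16 rows of the standard evaluation
#' table. A selector returning an empty subset yields a flagged `NA` row
#' rather than an error.
#'
#' @param ds A [spectral_dataset()] for one body region.
#' @param config A [model_matrix_config()].
#' @return A data frame with columns `region`, `model`, `n_vars`,
#'   `R2C_pct`, `RMSEC_pct`, `SDC`, `SEC`, `R2P_pct`, `RMSEP_pct`, `RPD`,
#'   `SDP`, `SEP`, `fit_grade`, `rpd_grade`, `note`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(100, physics = scene_physics(seed = 11))
#' tab <- run_model_matrix(trim_to_analysis_range(ds))
#' tab[, c("model", "n_vars", "R2P_pct", "RPD")]
#' }
#' @export
run_model_matrix <- function(ds, config = model_matrix_config()) {
  stopifnot(inherits(ds, "spectral_dataset"),
            inherits(config, "model_matrix_config"))
  rows <- list()
  for (pt in config$pretreatments) {
    dsp <- preprocess_dataset(ds, pt, window = config$sg_window,
                              order = config$sg_order)
    split <- split_dataset(dsp, config$n_cal, config$n_pred,
                           strategy = config$split_strategy,
                           seed = config$split_seed)
    cal <- ds_subset(dsp, rows = split$calibration)
    Xp <- dsp$spectra[split$prediction, , drop = FALSE]
    yp <- dsp$responses[split$prediction]
    for (sel in config$selectors) {
      name <- if (sel == "FW") sprintf("%s-PLSR", pt)
              else sprintf("%s-%s-PLSR", pt, sel)
      subset <- switch(
        sel,
        "FW" = wavelength_subset(seq_along(dsp$axis), dsp$axis, "FW", pt),
        "SPA" = tryCatch(
          spa_select(cal, config$spa_k_min, config$spa_k_max),
          error = function(e) NULL),
        "RC" = tryCatch(rc_select(cal, config$rc_n_keep),
                        error = function(e) NULL),
        "2D-COS" = tryCatch(suppressWarnings(
          autopeak_select(synchronous_spectrum(cal),
                          config$cos_max_peaks, config$cos_prominence)),
          error = function(e) NULL),
        stop("unknown selector: ", sel, call. = FALSE)
      )
      if (is.null(subset) || length(subset$indices) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = ds$region, model = name, n_vars = 0L,
          R2C_pct = NA_real_, RMSEC_pct = NA_real_, SDC = NA_real_,
          SEC = NA_real_, R2P_pct = NA_real_, RMSEP_pct = NA_real_,
          RPD = NA_real_, SDP = NA_real_, SEP = NA_real_,
          fit_grade = NA_character_, rpd_grade = NA_character_,
          note = "empty wavelength subset")
        next
      }
      idx <- subset$indices
      Xc <- cal$spectra[, idx, drop = FALSE]
      lv <- select_latent_variables(Xc, cal$responses,
                                    max_lv = config$max_lv,
                                    folds = config$cv_folds)
      model <- fit_plsr(Xc, cal$responses, lv)
      mc <- compute_metrics(cal$responses, predict(model, Xc),
                            "calibration")
      mp <- compute_metrics(yp, predict(model, Xp[, idx, drop = FALSE]),
                            "prediction")
      gr <- grade_model(list(r2_pred = mp$r2, rpd = mp$rpd))
      rows[[length(rows) + 1L]] <- data.frame(
        region = ds$region, model = name, n_vars = length(idx),
        R2C_pct = mc$r2, RMSEC_pct = mc$rmse, SDC = mc$sd, SEC = mc$se,
        R2P_pct = mp$r2, RMSEP_pct = mp$rmse, RPD = mp$rpd, SDP = mp$sd,
        SEP = mp$se, fit_grade = gr$fit_grade, rpd_grade = gr$rpd_grade,
        note = "")
    }
  }
  do.call(rbind, rows)
}

#' Select the optimal characteristic-wavelength model
#'
#' Ranks the characteristic-wavelength rows of a model-matrix table by
#' prediction-set R2 (higher better), then by the stability criterion
#' `|RMSEC - RMSEP|` (smaller better), then by RPD (higher better), and
#' returns the winning model name. Full-wavelength rows are excluded:
#' the point of the exercise is a model cheap enough for online
#' multispectral use.
#'
#' @param reports Data frame from [run_model_matrix()] (one region).
#' @return The winning model name (character scalar).
#' @export
select_optimal_model <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  cw <- reports[grepl("-(SPA|RC|2D-COS)-PLSR$", reports$model) &
                  is.finite(reports$R2P_pct), , drop = FALSE]
  if (!nrow(cw)) {
    stop("no characteristic-wavelength model rows available",
         call. = FALSE)
  }
  stability <- abs(cw$RMSEC_pct - cw$RMSEP_pct)
  ord <- order(-cw$R2P_pct, stability, -cw$RPD)
  cw$model[ord[1L]]
}

#' Published reference evaluation matrix
#'
#' The evaluation tables of a published carp scaling-rate study
#' (back/belly/tail regions, 16 PLSR models each), shipped as a
#' plain-text fixture. Used to validate the package's metric arithmetic:
#' the RPD identity `RPD = 100 * SD_P / RMSEP` and the stability
#' differences `|RMSEC - RMSEP|` can be recomputed from these printed
#' values.
#'
#' @return Data frame with columns `region`, `model`, `n_vars`,
#'   `R2C_pct`, `RMSEC_pct`, `SDC`, `SEC`, `R2P_pct`, `RMSEP_pct`, `RPD`,
#'   `SDP`, `SEP`.
#' @examples
#' ref <- reference_model_matrix()
#' subset(ref, region == "back" & model == "FD-PLSR")
#' @export
reference_model_matrix <- function() {
  path <- system.file("extdata", "reference_model_matrix.csv",
                      package = "scalespec", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
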