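# High-level glue: cohort -> preprocessed windows -> the four feature
# families -> fused matrix, plus ready-made model functions for
# run_experiment().

#' Preprocess a whole cohort
#'
#' @param cohort list of `list(ppg =, ecg =)` pairs from [generate_cohort()].
#' @param win_s window length in seconds.
#' @return list with `ppg` and `ecg`: named lists of `window_set`s keyed by
#'   subject id.
#' @export
preprocess_cohort <- function(cohort, win_s = 32) {
  ids <- vapply(cohort, function(p) p$ppg$subject_id, character(1))
  ppg <- lapply(cohort, function(p) preprocess_record(p$ppg, win_s = win_s))
  ecg <- lapply(cohort, function(p) preprocess_record(p$ecg, win_s = win_s))
  names(ppg) <- ids; names(ecg) <- ids
  list(ppg = ppg, ecg = ecg)
}

#' Extract the four hybrid feature families for a cohort
#'
#' @param windows output of [preprocess_cohort()].
#' @return named list of four `rr_features`: `ppg_ps`, `ppg_mf`, `ecg_ps`,
#'   `ecg_mf`.
#' @export
cohort_features <- function(windows) {
  list(ppg_ps = build_feature_matrix(windows$ppg, "ps", "ppg"),
       ppg_mf = build_feature_matrix(windows$ppg, "mf", "ppg"),
       ecg_ps = build_feature_matrix(windows$ecg, "ps", "ecg"),
       ecg_mf = build_feature_matrix(windows$ecg, "mf", "ecg"))
}

#' Model function: EGPR with optional RNCA feature selection
#'
#' Returns a closure suitable for [run_experiment()]: on each call it
#' (optionally) selects features by RNCA on the training part, fits EGPR on
#' the selected columns, and predicts the test rows with 95% intervals.
#'
#' @param select apply RNCA feature selection (default `TRUE`).
#' @param nca_config an [rnca_config()].
#' @param lambda optional fixed RNCA lambda; `NULL` tunes by CV on the first
#'   call and reuses the tuned value afterwards.
#' @param egpr an [egpr_control()].
#' @return function `(X_train, y_train, X_test)` -> prediction data.frame.
#' @export
model_egpr <- function(select = TRUE, nca_config = rnca_config(),
                       lambda = NULL, egpr = egpr_control()) {
  env <- new.env()
  env$lambda <- lambda
  function(Xtr, ytr, Xte) {
    cols <- seq_len(ncol(Xtr))
    if (select) {
      wts <- rnca_select(Xtr, ytr, nca_config, lambda = env$lambda)
      env$lambda <- wts$lambda_b
      cols <- wts$selection
    }
    fit <- egpr_fit(Xtr[, cols, drop = FALSE], ytr, egpr)
    predict(fit, Xte[, cols, drop = FALSE])
  }
}

#' Model function: constant (train-mean) predictor baseline
#'
#' @return function `(X_train, y_train, X_test)` -> numeric predictions.
#' @export
model_constant <- function() {
  function(Xtr, ytr, Xte) rep(mean(ytr), nrow(Xte))
}
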