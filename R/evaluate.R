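#' Experiment configuration for repeated grouped splits
#'
#' @param split training fraction (default 0.8).
#' @param repetitions number of repeated random splits (default 30).
#' @param seed master seed; the split of repetition r is a pure function of
#'   `(seed, r)` and the subject ids.
#' @param group_by `"subject"` (default; no subject straddles train and
#'   test) or `"sample"`.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(split = 0.8, repetitions = 30, seed = 1L,
                              group_by = c("subject", "sample")) {
  stopifnot(split > 0, split < 1, repetitions >= 1)
  structure(list(split = split, repetitions = repetitions,
                 seed = as.integer(seed), group_by = match.arg(group_by)),
            class = "experiment_config")
}

split_indices <- function(meta, config, rep_idx) {
  set.seed(config$seed * 1000L + rep_idx)
  if (config$group_by == "subject") {
    subjects <- sort(unique(meta$subject))
    n_tr <- floor(config$split * length(subjects))
    if (n_tr < 1 || n_tr >= length(subjects))
      stop("too few subjects for a nonempty train/test split", call. = FALSE)
    tr_sub <- sample(subjects, n_tr)
    which(meta$subject %in% tr_sub)
  } else {
    n <- nrow(meta)
    sort(sample.int(n, floor(config$split * n)))
  }
}

#' Run the repeated-split experiment
#'
#' For each repetition r, the samples are split 80/20 (grouped by subject by
#' default), `model_fn` is fitted on the training part and its test MAE
#' recorded; the table aggregates the mean and SD of the MAE across
#' repetitions.
#'
#' @param features an `rr_features` / `rr_fused` object with reference RR in
#'   `meta$rr`.
#' @param model_fn function `(X_train, y_train, X_test)` returning either a
#'   numeric prediction vector or a data.frame with a `mean` column (and
#'   optionally `sd`, `ci_low`, `ci_high`).
#' @param config an [experiment_config()].
#' @return a `result_table`: list with `mae_mean`, `mae_sd`, `per_rep`
#'   (per-repetition MAEs), and `last_predictions` (test predictions of the
#'   final repetition, with targets attached).
#' @export
run_experiment <- function(features, model_fn, config = experiment_config()) {
  ok <- is.finite(features$meta$rr)
  X <- features$X[ok, , drop = FALSE]
  meta <- features$meta[ok, , drop = FALSE]
  y <- meta$rr
  per_rep <- numeric(config$repetitions)
  last_pred <- NULL
  for (r in seq_len(config$repetitions)) {
    tr <- split_indices(meta, config, r)
    te <- setdiff(seq_len(nrow(X)), tr)
    pred <- model_fn(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
    yhat <- if (is.data.frame(pred)) pred$mean else as.numeric(pred)
    per_rep[r] <- mae(y[te], yhat)
    if (r == config$repetitions) {
      last_pred <- if (is.data.frame(pred)) pred else data.frame(mean = yhat)
      last_pred$actual <- y[te]
    }
  }
  structure(list(mae_mean = mean(per_rep), mae_sd = sd(per_rep),
                 per_rep = per_rep, last_predictions = last_pred,
                 config = config),
            class = "result_table")
}

#' Summarize predictive confidence intervals
#'
#' Means and SDs across test samples of the predicted RR, the CI lower and
#' upper bounds, and the CI width — the uncertainty summary row of the
#' pipeline's reporting.
#'
#' @param predictions data.frame with `mean`, `ci_low`, `ci_high`.
#' @return data.frame with one row per quantity (`rr`, `ci_low`, `ci_high`,
#'   `ci_width`), columns `mean` and `sd`.
#' @export
ci_summary <- function(predictions) {
  if (!nrow(predictions)) stop("empty predictions", call. = FALSE)
  need <- c("mean", "ci_low", "ci_high")
  if (!all(need %in% names(predictions)))
    stop("predictions must carry mean, ci_low, ci_high", call. = FALSE)
  width <- predictions$ci_high - predictions$ci_low
  data.frame(
    quantity = c("rr", "ci_low", "ci_high", "ci_width"),
    mean = c(mean(predictions$mean), mean(predictions$ci_low),
             mean(predictions$ci_high), mean(width)),
    sd = c(sd(predictions$mean), sd(predictions$ci_low),
           sd(predictions$ci_high), sd(width)))
}

#' One-way ANOVA with Tukey–Kramer multiple comparisons
#'
#' Compares per-repetition MAE distributions across model configurations:
#' standard one-way decomposition (SS, df, MS), F statistic, p-value, and
#' pairwise Tukey honest significant differences.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return an `anova_result`: list with `table` (Group/Error/Total rows),
#'   `F`, `p`, `group_means`, `tukey` (pairwise comparison table).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups), lengths(groups))))
  fit <- aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  ss_g <- an["group", "Sum Sq"]; ss_e <- an["Residuals", "Sum Sq"]
  df_g <- an["group", "Df"]; df_e <- an["Residuals", "Df"]
  Fv <- an["group", "F value"]; p <- an["group", "Pr(>F)"]
  if (ss_g < 1e-12) { Fv <- 0; p <- 1 }   # all-constant convention
  tab <- data.frame(
    source = c("Group", "Error", "Total"),
    SS = c(ss_g, ss_e, ss_g + ss_e),
    df = c(df_g, df_e, df_g + df_e),
    MS = c(ss_g / df_g, ss_e / df_e, NA))
  structure(list(table = tab, F = Fv, p = p,
                 group_means = tapply(d$value, d$group, mean),
                 tukey = as.data.frame(TukeyHSD(fit)$group)),
            class = "anova_result")
}
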