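#' Fuse feature-family matrices into one matrix
#'
#' Column-wise concatenation of the four feature families (PPG-PS, PPG-MF,
#' ECG-PS, ECG-MF) aligned on (subject, window) keys: 972 columns at the
#' default dimensions. Rows missing from any block are dropped with a
#' message.
#'
#' @param ... two or more `rr_features` objects (typically four).
#' @return an `rr_fused` object: `X`, `meta`, `blocks` (named column counts).
#' @export
fuse <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !inherits(mats[[1]], "rr_features"))
    mats <- mats[[1]]
  if (length(mats) < 2L) stop("fusion needs at least two feature sets", call. = FALSE)
  if (any(vapply(mats, function(m) nrow(m$X) == 0L, logical(1))))
    stop("alignment error: empty feature matrix", call. = FALSE)
  keyof <- function(m) paste(m$meta$subject, m$meta$window, sep = "/")
  keys <- Reduce(intersect, lapply(mats, keyof))
  if (!length(keys)) stop("alignment error: no common (subject, window) keys",
                          call. = FALSE)
  dropped <- max(vapply(mats, function(m) nrow(m$X), integer(1))) - length(keys)
  if (dropped > 0) message("fusion dropped ", dropped, " unmatched rows")
  aligned <- lapply(mats, function(m) {
    i <- match(keys, keyof(m))
    list(X = m$X[i, , drop = FALSE], meta = m$meta[i, , drop = FALSE])
  })
  X <- do.call(cbind, lapply(aligned, function(a) a$X))
  blocks <- vapply(mats, function(m) ncol(m$X), integer(1))
  names(blocks) <- vapply(mats, function(m) paste(m$modality, m$family, sep = "_"),
                          character(1))
  structure(list(X = X, meta = aligned[[1]]$meta, blocks = blocks),
            class = c("rr_fused", "rr_features"))
}

#' Robust and standard losses for NCA regression
#'
#' `"robust"` is \eqn{\zeta(a,b) = 1 - \exp(-|a-b|)} (bounded, so distant
#' outliers cannot dominate); `"abs"` and `"squared"` are the usual
#' alternatives.
#'
#' @param y numeric targets.
#' @param loss loss name.
#' @return n x n matrix of pairwise losses.
#' @export
nca_loss_matrix <- function(y, loss = c("robust", "abs", "squared")) {
  loss <- match.arg(loss)
  d <- abs(outer(y, y, "-"))
  switch(loss, robust = 1 - exp(-d), abs = d, squared = d^2)
}

#' Leave-one-out NCA regression loss
#'
#' Soft-neighbor leave-one-out loss: with weighted L1 distances
#' \eqn{D_w(x_i,x_j) = \sum_k w_k^2 |x_{ik} - x_{jk}|} and kernel
#' \eqn{k(z)=\exp(-z/\sigma)}, each point picks a reference point among the
#' others with probability \eqn{\gamma_{ij}}, and
#' \eqn{L_i = \sum_{j \ne i} \gamma_{ij}\, loss(y_i, y_j)}.
#'
#' @param w numeric weight vector (length p).
#' @param X standardized n x p matrix, n >= 2.
#' @param y numeric targets.
#' @param sigma kernel width (default 1).
#' @param loss loss name (see [nca_loss_matrix()]).
#' @return list with `Li` (per-sample losses), `mean` and `gamma`.
#' @export
nca_loo_loss <- function(w, X, y, sigma = 1, loss = "robust") {
  if (nrow(X) < 2) stop("leave-one-out loss undefined for n < 2", call. = FALSE)
  Lmat <- nca_loss_matrix(y, loss)
  r <- nca_loss_cpp(X, as.numeric(w), Lmat, sigma)
  list(Li = r$Li, mean = mean(r$Li), gamma = r$gamma)
}

#' Regularized NCA objective
#'
#' \eqn{F(w) = \frac1n \sum_i L_i + \lambda \sum_k w_k^2}.
#'
#' @inheritParams nca_loo_loss
#' @param lambda regularization parameter (> 0).
#' @param gradient also return the analytic gradient.
#' @return objective value; with `gradient = TRUE`, a list
#'   `(objective, gradient)`.
#' @export
nca_objective <- function(w, X, y, lambda, sigma = 1, loss = "robust",
                          gradient = FALSE) {
  if (nrow(X) < 2) stop("leave-one-out loss undefined for n < 2", call. = FALSE)
  Lmat <- nca_loss_matrix(y, loss)
  r <- nca_obj_grad_cpp(X, as.numeric(w), Lmat, sigma, lambda)
  if (gradient) list(objective = r$objective, gradient = as.numeric(r$gradient))
  else r$objective
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  list(mu = mu, sd = sd_)
}
standardize_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")

#' RNCA configuration
#'
#' @param lambda_grid candidate regularization values; default 10
#'   log-spaced points in [1e-5, 1e-1].
#' @param folds cross-validation folds for lambda tuning.
#' @param sigma kernel width on standardized features.
#' @param loss loss name (default `"robust"`).
#' @param maxit optimizer iteration cap.
#' @param reltol objective convergence tolerance.
#' @param threshold relative selection threshold (fraction of max |w|).
#' @param tune_maxit iteration cap used inside lambda tuning (cheaper fits
#'   suffice for ranking lambdas).
#' @param tune_rows optional row cap for lambda tuning (random subsample).
#' @param seed RNG seed for fold assignment / subsampling.
#' @return an `rnca_config` list.
#' @export
rnca_config <- function(lambda_grid = 10^seq(-5, -1, length.out = 10),
                        folds = 5, sigma = 1, loss = "robust",
                        maxit = 100, reltol = 1e-6, threshold = 0.1,
                        tune_maxit = 30, tune_rows = NULL, seed = 1L) {
  stopifnot(all(lambda_grid > 0), !is.unsorted(lambda_grid))
  structure(list(lambda_grid = lambda_grid, folds = folds, sigma = sigma,
                 loss = loss, maxit = maxit, reltol = reltol,
                 threshold = threshold, tune_maxit = tune_maxit,
                 tune_rows = tune_rows, seed = as.integer(seed)),
            class = "rnca_config")
}

#' Fit NCA feature weights at a fixed regularization
#'
#' Minimizes the regularized leave-one-out objective by L-BFGS from the
#' all-ones start; the objective is smooth in `w` (the absolute values in
#' the distance act on the data, not the weights), so analytic gradients are
#' exact. Deterministic given inputs.
#'
#' @param X standardized n x p matrix.
#' @param y numeric targets.
#' @param lambda regularization parameter.
#' @param config an [rnca_config()].
#' @param maxit optional iteration cap override.
#' @return an `nca_weights` object: `w`, `lambda`, `sigma`, `loss`,
#'   `objective` (trajectory endpoints), `converged`.
#' @export
fit_nca <- function(X, y, lambda, config = rnca_config(), maxit = NULL) {
  if (is.null(maxit)) maxit <- config$maxit
  Lmat <- nca_loss_matrix(y, config$loss)
  sigma <- config$sigma
  last <- new.env()
  evalf <- function(w) {
    r <- nca_obj_grad_cpp(X, w, Lmat, sigma, lambda)
    last$w <- w; last$r <- r
    r
  }
  fn <- function(w) {
    if (!is.null(last$w) && identical(w, last$w)) return(last$r$objective)
    evalf(w)$objective
  }
  gr <- function(w) {
    if (!is.null(last$w) && identical(w, last$w)) return(as.numeric(last$r$gradient))
    as.numeric(evalf(w)$gradient)
  }
  w0 <- rep(1, ncol(X))
  f0 <- fn(w0)
  opt <- optim(w0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = config$reltol / .Machine$double.eps))
  converged <- opt$convergence == 0
  if (!converged)
    warning("NCA optimizer stopped before convergence; returning best-so-far")
  structure(list(w = opt$par, lambda = lambda, sigma = sigma,
                 loss = config$loss,
                 objective = c(initial = f0, final = opt$value),
                 converged = converged),
            class = "nca_weights")
}

#' Tune the RNCA regularization parameter by cross-validation
#'
#' For each lambda on the grid, k-fold cross-validation: fit NCA weights on
#' the training folds (standardized on those folds only) and score the held
#' -out fold with the robust loss against soft-neighbor reference points from
#' the training folds. Returns the grid argmin of the mean fold loss; ties
#' break toward the smaller lambda.
#'
#' @param X raw (unstandardized) n x p matrix.
#' @param y numeric targets.
#' @param config an [rnca_config()].
#' @return list with `lambda_b`, `cv_loss` (per-lambda mean), `cv_table`
#'   (lambda x fold losses).
#' @export
tune_lambda <- function(X, y, config = rnca_config()) {
  n <- nrow(X)
  if (n < config$folds) stop("fewer samples than folds", call. = FALSE)
  set.seed(config$seed)
  if (!is.null(config$tune_rows) && config$tune_rows < n) {
    keep <- sort(sample.int(n, config$tune_rows))
    X <- X[keep, , drop = FALSE]; y <- y[keep]; n <- length(keep)
  }
  fold <- sample(rep(seq_len(config$folds), length.out = n))
  cv <- matrix(NA_real_, length(config$lambda_grid), config$folds,
               dimnames = list(format(config$lambda_grid, digits = 3), NULL))
  for (li in seq_along(config$lambda_grid)) {
    for (k in seq_len(config$folds)) {
      tr <- fold != k
      s <- standardize_fit(X[tr, , drop = FALSE])
      Xtr <- standardize_apply(X[tr, , drop = FALSE], s)
      Xva <- standardize_apply(X[!tr, , drop = FALSE], s)
      # tuning fits are deliberately truncated; ranking lambdas does not
      # need full convergence, so the non-convergence warning is muted here
      fitk <- suppressWarnings(
        fit_nca(Xtr, y[tr], config$lambda_grid[li], config,
                maxit = config$tune_maxit))
      Lva <- switch(config$loss,
                    robust = 1 - exp(-abs(outer(y[!tr], y[tr], "-"))),
                    abs = abs(outer(y[!tr], y[tr], "-")),
                    squared = outer(y[!tr], y[tr], "-")^2)
      lv <- nca_predict_loss_cpp(Xtr, Xva, Lva, fitk$w, config$sigma)
      cv[li, k] <- mean(lv)
    }
  }
  means <- rowMeans(cv)
  list(lambda_b = config$lambda_grid[which.min(means)], cv_loss = means,
       cv_table = cv)
}

#' Select high-weight features
#'
#' Default rule: keep features with \eqn{|w_k| \ge} `threshold` x max |w|.
#' An empty selection falls back to the top 10 features by |w| with a
#' warning.
#'
#' @param weights an `nca_weights` from [fit_nca()].
#' @param threshold relative threshold (default 0.1), or `NULL` to use
#'   `absolute`.
#' @param absolute optional absolute threshold on |w|.
#' @return integer vector of selected column indices (also stored on the
#'   weights object under `$selection` by [rnca_select()]).
#' @export
select_features <- function(weights, threshold = 0.1, absolute = NULL) {
  aw <- abs(weights$w)
  thr <- if (!is.null(absolute)) absolute else threshold * max(aw)
  idx <- which(aw >= thr)
  if (!length(idx)) {
    warning("empty selection at threshold; falling back to top-10 features")
    idx <- order(aw, decreasing = TRUE)[seq_len(min(10L, length(aw)))]
  }
  sort(idx)
}

#' Full RNCA pipeline: tune lambda, fit, threshold
#'
#' Tunes lambda by cross-validation with the robust loss, refits on the full
#' (standardized) training matrix at the tuned lambda, and thresholds the
#' weights.
#'
#' @param X raw training feature matrix.
#' @param y training targets.
#' @param config an [rnca_config()].
#' @param lambda optional fixed lambda (skips tuning).
#' @return an `nca_weights` with `selection` (indices), `lambda_b`, the CV
#'   table, and the standardization constants used.
#' @export
rnca_select <- function(X, y, config = rnca_config(), lambda = NULL) {
  tune <- NULL
  if (is.null(lambda)) {
    tune <- tune_lambda(X, y, config)
    lambda <- tune$lambda_b
  }
  s <- standardize_fit(X)
  w <- fit_nca(standardize_apply(X, s), y, lambda, config)
  w$selection <- select_features(w, threshold = config$threshold)
  w$lambda_b <- lambda
  w$cv <- tune
  w$standardize <- s
  w
}

#' Arithmetic fusion of per-family predictions
#'
#' Element-wise mean of aligned prediction vectors from the four
#' single-family models; the comparison baseline to feature-level fusion.
#'
#' @param ... numeric prediction vectors of equal length (or one list).
#' @return numeric vector of fused predictions.
#' @export
arithmetic_fusion <- function(...) {
  preds <- list(...)
  if (length(preds) == 1L && is.list(preds[[1]])) preds <- preds[[1]]
  len <- unique(lengths(preds))
  if (length(len) != 1L)
    stop("alignment error: prediction vectors differ in length", call. = FALSE)
  rowMeans(do.call(cbind, preds))
}
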