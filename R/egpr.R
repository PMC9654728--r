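#' Squared-exponential kernel matrix
#'
#' \eqn{K_{ij} = \sigma_f^2 \exp(-\|x_i - x'_j\|^2 / (2\eta^2))}. The signal
#' variance (kernel prefactor) is kept distinct from the observation-noise
#' variance, which enters only on the diagonal of the training covariance.
#'
#' @param Xa,Xb matrices with equal column counts (rows = points).
#' @param eta kernel length scale (> 0).
#' @param sf2 signal variance (> 0).
#' @return `nrow(Xa)` x `nrow(Xb)` kernel matrix.
#' @export
kernel_matrix <- function(Xa, Xb, eta, sf2) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  if (ncol(Xa) != ncol(Xb)) stop("feature-dimension mismatch", call. = FALSE)
  d2 <- outer(rowSums(Xa^2), rowSums(Xb^2), "+") - 2 * tcrossprod(Xa, Xb)
  d2[d2 < 0] <- 0
  sf2 * exp(-d2 / (2 * eta^2))
}

# Cholesky of K + s2 I with escalating jitter.
chol_jitter <- function(M, jitter0 = 1e-10, jitter_max = 1e-6) {
  sc <- mean(diag(M))
  j <- jitter0
  repeat {
    R <- tryCatch(chol(M + diag(j * sc, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = j * sc))
    if (j >= jitter_max) stop("covariance factorization failed after max jitter",
                              call. = FALSE)
    j <- j * 10
  }
}

basis_matrix <- function(X, basis) {
  n <- nrow(as.matrix(X))
  switch(basis,
         constant = matrix(1, n, 1),
         linear = cbind(1, as.matrix(X)),
         stop("unknown basis: ", basis, call. = FALSE))
}

#' Generalized-least-squares basis weights
#'
#' Profiles out the explicit-basis coefficients for given kernel
#' hyperparameters: \eqn{\hat w = (\Theta^T M^{-1} \Theta)^{-1} \Theta^T
#' M^{-1} y} with \eqn{M = C + \sigma^2 I}.
#'
#' @param eta,sf2,s2 kernel length scale, signal variance, noise variance.
#' @param X training inputs; `y` training targets.
#' @param Theta basis matrix (full column rank).
#' @return numeric coefficient vector.
#' @export
profile_basis_weights <- function(eta, sf2, s2, X, y, Theta) {
  M <- kernel_matrix(X, X, eta, sf2) + diag(s2, nrow(as.matrix(X)))
  R <- chol_jitter(M)$R
  Minv_T <- backsolve(R, forwardsolve(t(R), Theta))
  Minv_y <- backsolve(R, forwardsolve(t(R), y))
  A <- crossprod(Theta, Minv_T)
  if (rcond(A) < 1e-12) stop("ill-posed basis: Theta rank deficient", call. = FALSE)
  as.numeric(solve(A, crossprod(Theta, Minv_y)))
}

#' Log marginal likelihood of the exact GP model
#'
#' \eqn{-\frac12 \log|M| - \frac n2 \log 2\pi - \frac12 (y-\Theta w)^T M^{-1}
#' (y-\Theta w)} with \eqn{M = C + \sigma^2 I}, computed via triangular
#' factorization.
#'
#' @inheritParams profile_basis_weights
#' @param w basis coefficient vector.
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(eta, sf2, s2, w, X, y, Theta) {
  n <- length(y)
  M <- kernel_matrix(X, X, eta, sf2) + diag(s2, n)
  R <- chol_jitter(M)$R
  r <- y - as.numeric(Theta %*% w)
  alpha <- backsolve(R, forwardsolve(t(R), r))
  -sum(log(diag(R))) - n / 2 * log(2 * pi) - 0.5 * sum(r * alpha)
}

#' EGPR fitting control
#'
#' @param basis `"constant"` (default) or `"linear"` explicit mean basis.
#' @param restarts number of optimizer restarts (first start is data-driven:
#'   eta = median pairwise distance, sf2 = var(y), s2 = 0.1 var(y); later
#'   starts perturb it).
#' @param maxit L-BFGS iteration cap per restart.
#' @param optimize set `FALSE` to keep the initial (or `fixed`) values.
#' @param fixed optional named list `(eta, sf2, s2)` overriding
#'   initialization (on the internal standardized-target scale when
#'   `standardize_y = TRUE`).
#' @param standardize_y center/scale targets internally (default `TRUE`).
#' @param basis_uncertainty include the explicit-basis correction in the
#'   predictive variance (default `TRUE`).
#' @param ci_level predictive interval level (default 0.95).
#' @param seed seed for restart perturbations.
#' @return an `egpr_control` list.
#' @export
egpr_control <- function(basis = "constant", restarts = 3, maxit = 100,
                         optimize = TRUE, fixed = NULL, standardize_y = TRUE,
                         basis_uncertainty = TRUE, ci_level = 0.95, seed = 1L) {
  structure(list(basis = basis, restarts = restarts, maxit = maxit,
                 optimize = optimize, fixed = fixed,
                 standardize_y = standardize_y,
                 basis_uncertainty = basis_uncertainty,
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "egpr_control")
}

# negative profiled log marginal likelihood and gradient in log-parameter
# space theta = (log eta, log sf2, log s2); w is profiled out by GLS, so the
# envelope theorem gives the gradient holding w fixed.
egpr_nll <- function(theta, X, y, Theta) {
  eta <- exp(theta[1]); sf2 <- exp(theta[2]); s2 <- exp(theta[3])
  n <- length(y)
  C <- kernel_matrix(X, X, eta, sf2)
  M <- C + diag(s2, n)
  ch <- chol_jitter(M)
  R <- ch$R
  Minv_T <- backsolve(R, forwardsolve(t(R), Theta))
  Minv_y <- backsolve(R, forwardsolve(t(R), y))
  A <- crossprod(Theta, Minv_T)
  w <- as.numeric(solve(A, crossprod(Theta, Minv_y)))
  r <- y - as.numeric(Theta %*% w)
  alpha <- backsolve(R, forwardsolve(t(R), r))
  nll <- sum(log(diag(R))) + n / 2 * log(2 * pi) + 0.5 * sum(r * alpha)

  Minv <- chol2inv(R)
  # dM/dlog(eta) = C * d2 / eta^2 ; dM/dlog(sf2) = C ; dM/dlog(s2) = s2 I
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  dM_eta <- C * d2 / eta^2
  grad_of <- function(dM) {
    # d nll/dtheta = 0.5 tr(Minv dM) - 0.5 alpha' dM alpha
    0.5 * sum(Minv * dM) - 0.5 * as.numeric(crossprod(alpha, dM %*% alpha))
  }
  g <- c(grad_of(dM_eta), grad_of(C), grad_of(diag(s2, n)))
  list(value = nll, gradient = g, w = w)
}

#' Fit an exact Gaussian process regression model
#'
#' Maximizes the log marginal likelihood over (length scale eta, signal
#' variance sf2, noise variance s2) by L-BFGS in log-parameter space with
#' analytic gradients, the explicit-basis coefficients profiled out by
#' generalized least squares at every step. Multi-start with deterministic
#' perturbations; the training-covariance Cholesky factor and the weight
#' vector phi are cached for prediction.
#'
#' @param X training inputs (rows = samples); standardized internally.
#' @param y training targets (bpm).
#' @param control an [egpr_control()].
#' @return an `egpr_model`.
#' @export
egpr_fit <- function(X, y, control = egpr_control()) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3) stop("EGPR needs at least 3 training points", call. = FALSE)
  sx <- standardize_fit(X)
  Xs <- standardize_apply(X, sx)
  ymu <- if (control$standardize_y) mean(y) else 0
  ysd <- if (control$standardize_y) max(sd(y), 1e-8) else 1
  ys <- (y - ymu) / ysd
  Theta <- basis_matrix(Xs, control$basis)

  sub <- Xs[seq_len(min(256L, n)), , drop = FALSE]
  med_d <- median(dist(sub))
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  init <- log(c(eta = med_d, sf2 = max(var(ys), 1e-6),
                s2 = max(0.1 * var(ys), 1e-6)))
  if (!is.null(control$fixed))
    init[names(control$fixed)] <- log(unlist(control$fixed))

  run_opt <- function(theta0) {
    last <- new.env()
    evalf <- function(th) { r <- egpr_nll(th, Xs, ys, Theta); last$th <- th; last$r <- r; r }
    fn <- function(th) {
      if (!is.null(last$th) && identical(th, last$th)) last$r$value else evalf(th)$value
    }
    gr <- function(th) {
      if (!is.null(last$th) && identical(th, last$th)) last$r$gradient else evalf(th)$gradient
    }
    opt <- tryCatch(
      optim(theta0, fn, gr, method = "L-BFGS-B",
            lower = log(c(1e-3, 1e-8, 1e-8)), upper = log(c(1e4, 1e4, 1e4)),
            control = list(maxit = control$maxit)),
      error = function(e) NULL)
    opt
  }

  lml0 <- -egpr_nll(init, Xs, ys, Theta)$value
  if (control$optimize) {
    set.seed(control$seed)
    starts <- list(init)
    if (control$restarts > 1)
      for (r in seq_len(control$restarts - 1))
        starts[[r + 1]] <- init + rnorm(3, 0, 0.7)
    fits <- lapply(starts, run_opt)
    vals <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
    if (all(!is.finite(vals)))
      stop("EGPR fit failed in all restarts", call. = FALSE)
    theta <- fits[[which.min(vals)]]$par
  } else theta <- init

  eta <- exp(theta[1]); sf2 <- exp(theta[2]); s2 <- exp(theta[3])
  final <- egpr_nll(theta, Xs, ys, Theta)
  M <- kernel_matrix(Xs, Xs, eta, sf2) + diag(s2, n)
  R <- chol_jitter(M)$R
  w <- final$w
  r <- ys - as.numeric(Theta %*% w)
  phi <- backsolve(R, forwardsolve(t(R), r))

  structure(list(eta = eta, sf2 = sf2, s2 = s2, w = w,
                 basis = control$basis, X = Xs, y = ys, Theta = Theta,
                 chol = R, phi = phi,
                 lml = -final$value, lml_init = lml0,
                 standardize_x = sx, y_mu = ymu, y_sd = ysd,
                 control = control),
            class = "egpr_model")
}

#' Predict from a fitted EGPR model
#'
#' Posterior mean \eqn{\theta(x_*)^T w + k_*^T \phi}; predictive variance
#' \eqn{\sigma_f^2 + \sigma^2 - k_*^T M^{-1} k_*} plus (by default) the
#' explicit-basis uncertainty correction. The interval is
#' mean +/- z(level) x sd, reported on the original target scale (bpm).
#'
#' @param object an `egpr_model`.
#' @param newdata matrix of new inputs (raw scale).
#' @param ... unused.
#' @return data.frame with `mean`, `sd`, `ci_low`, `ci_high` per row.
#' @export
predict.egpr_model <- function(object, newdata, ...) {
  Xs <- standardize_apply(as.matrix(newdata), object$standardize_x)
  if (ncol(Xs) != ncol(object$X))
    stop("feature-dimension mismatch", call. = FALSE)
  Kst <- kernel_matrix(object$X, Xs, object$eta, object$sf2)   # n x m
  Th_star <- basis_matrix(Xs, object$basis)
  mu <- as.numeric(Th_star %*% object$w) + as.numeric(crossprod(Kst, object$phi))
  V <- backsolve(object$chol, forwardsolve(t(object$chol), Kst))  # M^{ -1} k*
  var_f <- object$sf2 + object$s2 - colSums(Kst * V)
  if (isTRUE(object$control$basis_uncertainty)) {
    Minv_T <- backsolve(object$chol, forwardsolve(t(object$chol), object$Theta))
    A <- crossprod(object$Theta, Minv_T)
    Rmat <- t(Th_star) - crossprod(Minv_T, Kst)                 # p x m
    corr <- colSums(Rmat * solve(A, Rmat))
    var_f <- var_f + corr
  }
  var_f <- pmax(var_f, object$s2)
  z <- qnorm(1 - (1 - object$control$ci_level) / 2)
  mean_bpm <- mu * object$y_sd + object$y_mu
  sd_bpm <- sqrt(var_f) * object$y_sd
  data.frame(mean = mean_bpm, sd = sd_bpm,
             ci_low = mean_bpm - z * sd_bpm, ci_high = mean_bpm + z * sd_bpm)
}

#' Mean absolute error
#'
#' The pipeline's loss and headline accuracy metric (bpm). Under Gaussian
#' predictive distributions the posterior mean (= median) is the optimal
#' point estimate for this loss.
#'
#' @param y observed values; `y_hat` predictions, same length.
#' @return scalar MAE.
#' @export
mae <- function(y, y_hat) {
  if (!length(y)) stop("empty input", call. = FALSE)
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  mean(abs(y - y_hat))
}
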