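test_that("the squared-exponential kernel matches scalar evaluation", {
  X <- rand_matrix(3, 2, 1)
  K <- kernel_matrix(X, X, eta = 1.3, sf2 = 2.1)
  for (i in 1:3) for (j in 1:3)
    expect_equal(K[i, j],
                 2.1 * exp(-sum((X[i, ] - X[j, ])^2) / (2 * 1.3^2)),
                 tolerance = 1e-12)
  expect_equal(diag(K), rep(2.1, 3))
  far <- kernel_matrix(matrix(0, 1, 2), matrix(100, 1, 2), 1, 1)
  expect_lt(far[1, 1], 1e-300)
  expect_error(kernel_matrix(X, matrix(0, 2, 3), 1, 1), "dimension")
})

test_that("profiled basis weights solve the generalized least squares", {
  X <- rand_matrix(12, 2, 2)
  y <- rnorm(12, mean = 3)
  Theta <- matrix(1, 12, 1)
  # negligible kernel: GLS degenerates to the plain mean
  w0 <- profile_basis_weights(1e-3, 1e-8, 1, X, y, Theta)
  expect_equal(w0, mean(y), tolerance = 1e-6)
  # dense-matrix oracle
  M <- kernel_matrix(X, X, 0.9, 1.7) + diag(0.3, 12)
  w_direct <- solve(t(Theta) %*% solve(M, Theta), t(Theta) %*% solve(M, y))
  expect_equal(profile_basis_weights(0.9, 1.7, 0.3, X, y, Theta),
               as.numeric(w_direct), tolerance = 1e-8)
  # exact linear trend with a linear basis leaves ~no residual
  Th2 <- cbind(1, X)
  y_lin <- 2 + X %*% c(1, -0.5)
  w_lin <- profile_basis_weights(1, 1, 1e-6, X, as.numeric(y_lin), Th2)
  expect_equal(as.numeric(Th2 %*% w_lin), as.numeric(y_lin), tolerance = 1e-4)
  expect_error(profile_basis_weights(1, 1, 0.1, X, y,
                                     cbind(rep(1, 12), rep(1, 12))), "ill-posed")
})

test_that("log marginal likelihood matches the dense formula", {
  expect_equal(log_marginal_likelihood(1, 2, 0.5, w = 4.2, X = matrix(0, 1, 1),
                                       y = 4.2, Theta = matrix(1, 1, 1)),
               -0.5 * log(2.5) - 0.5 * log(2 * pi), tolerance = 1e-9)
  X <- rand_matrix(15, 2, 3); y <- rnorm(15); Theta <- matrix(1, 15, 1)
  M <- kernel_matrix(X, X, 1.1, 1.5) + diag(0.2, 15)
  r <- y - 0.3
  direct <- -0.5 * determinant(M)$modulus[1] - 15 / 2 * log(2 * pi) -
    0.5 * as.numeric(t(r) %*% solve(M, r))
  expect_equal(log_marginal_likelihood(1.1, 1.5, 0.2, 0.3, X, y, Theta),
               direct, tolerance = 1e-8)
  jittered <- log_marginal_likelihood(1.1, 1.5, 0.2 + 1e-10, 0.3, X, y, Theta)
  expect_equal(jittered, direct, tolerance = 1e-4)
})

test_that("prediction reproduces dense Gaussian conditioning", {
  set.seed(4)
  n <- 15
  X <- matrix(rnorm(n * 2), n)
  y <- sin(X[, 1]) + rnorm(n, 0, 0.1)
  fit <- egpr_fit(X, y, egpr_control(optimize = FALSE, standardize_y = FALSE,
                                     fixed = list(eta = 1.2, sf2 = 2, s2 = 0.05),
                                     basis_uncertainty = FALSE))
  Xn <- matrix(rnorm(8), 4)
  pr <- predict(fit, Xn)
  Xs <- rrfuse:::standardize_apply(X, fit$standardize_x)
  Xns <- rrfuse:::standardize_apply(Xn, fit$standardize_x)
  M <- kernel_matrix(Xs, Xs, 1.2, 2) + diag(0.05, n)
  one <- rep(1, n)
  w <- as.numeric(solve(t(one) %*% solve(M, one), t(one) %*% solve(M, y)))
  Ks <- kernel_matrix(Xns, Xs, 1.2, 2)
  mu <- w + as.numeric(Ks %*% solve(M, y - w))
  v <- 2 + 0.05 - diag(Ks %*% solve(M, t(Ks)))
  expect_equal(pr$mean, mu, tolerance = 1e-8)
  expect_equal(pr$sd^2, v, tolerance = 1e-7)
  expect_true(all(pr$ci_low <= pr$mean & pr$mean <= pr$ci_high))
  expect_true(all(pr$sd >= sqrt(0.05) - 1e-9))
  expect_equal(pr$ci_high - pr$mean, 1.96 * pr$sd, tolerance = 1e-3)
})

test_that("prediction interpolates near-noiseless data and reverts to the prior", {
  set.seed(6)
  X <- matrix(seq(-2, 2, length.out = 10), 10)
  y <- X[, 1]^2
  fit <- egpr_fit(X, y, egpr_control(optimize = FALSE,
                                     fixed = list(eta = 0.5, sf2 = 4, s2 = 1e-6)))
  at_train <- predict(fit, X)
  expect_equal(at_train$mean, y, tolerance = 1e-3)
  far <- predict(fit, matrix(100, 1, 1))
  expect_equal(far$mean, fit$w * fit$y_sd + fit$y_mu, tolerance = 1e-6)
  expect_gte(far$sd^2, 4 * fit$y_sd^2 * 0.999)  # reverts to sf2 + s2 (+ basis term)
})

test_that("hyperparameter fitting is deterministic and improves the evidence", {
  set.seed(10)
  X <- matrix(runif(60, -2, 2), 60)
  K <- kernel_matrix(X, X, 0.8, 1.5) + diag(0.1, 60)
  y <- as.numeric(t(chol(K)) %*% rnorm(60))
  f1 <- egpr_fit(X, y, egpr_control(restarts = 2))
  f2 <- egpr_fit(X, y, egpr_control(restarts = 2))
  expect_identical(f1[c("eta", "sf2", "s2")], f2[c("eta", "sf2", "s2")])
  expect_gte(f1$lml, f1$lml_init)
})

test_that("pure-noise targets are absorbed by the noise variance", {
  frac <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(runif(80, -2, 2), 80)
    y <- rnorm(80)
    f <- egpr_fit(X, y, egpr_control(restarts = 1))
    f$sf2 / f$s2 < 1
  }, logical(1))
  expect_gte(mean(frac), 0.8)
})

test_that("MAE behaves as the loss the posterior mean minimizes", {
  expect_equal(mae(c(10, 20), c(12, 16)), 3.0)
  expect_equal(mae(1:5, 1:5), 0)
  expect_error(mae(numeric(0), numeric(0)), "empty")
  set.seed(20)
  y <- rnorm(4000, mean = 7, sd = 2)
  for (delta in c(-0.5, 0.5))
    expect_lt(mean(abs(y - 7)), mean(abs(y - (7 + delta))))
})

test_that("predictive intervals achieve nominal coverage on GP draws", {
  set.seed(99)
  n <- 500
  X <- matrix(runif(n, -2, 2), n)
  K <- kernel_matrix(X, X, 0.8, 1.5) + diag(0.2, n)
  y <- as.numeric(t(chol(K)) %*% rnorm(n))
  tr <- 1:300; te <- 301:500
  eta_std <- 0.8 / sd(X[tr, 1])
  fit <- egpr_fit(X[tr, , drop = FALSE], y[tr],
                  egpr_control(optimize = FALSE, standardize_y = FALSE,
                               fixed = list(eta = eta_std, sf2 = 1.5, s2 = 0.2)))
  pr <- predict(fit, X[te, , drop = FALSE])
  coverage <- mean(y[te] >= pr$ci_low & y[te] <= pr$ci_high)
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.98)
})
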