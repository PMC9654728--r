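mk_features <- function(n, p, modality, family, seed, rr = NULL, subj = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0(modality, "_", family, seq_len(p))
  if (is.null(subj)) subj <- sprintf("s%02d", rep(seq_len(n %/% 2 + 1), each = 2)[seq_len(n)])
  meta <- data.frame(subject = subj, window = ave(seq_len(n), subj, FUN = seq_along),
                     rr = if (is.null(rr)) runif(n, 8, 25) else rr)
  structure(list(X = X, meta = meta, family = family, modality = modality),
            class = "rr_features")
}

test_that("fusion concatenates aligned blocks into 972 columns", {
  n <- 10
  parts <- list(mk_features(n, 256, "ppg", "ps", 1),
                mk_features(n, 230, "ppg", "mf", 2),
                mk_features(n, 256, "ecg", "ps", 3),
                mk_features(n, 230, "ecg", "mf", 4))
  for (i in 2:4) parts[[i]]$meta[c("subject", "window")] <-
    parts[[1]]$meta[c("subject", "window")]
  fused <- fuse(parts)
  expect_equal(dim(fused$X), c(n, 972L))
  expect_equal(unname(fused$blocks), c(256L, 230L, 256L, 230L))
  # permuted rows in one block realign by key
  perm <- sample(n)
  shuffled <- parts
  shuffled[[3]]$X <- shuffled[[3]]$X[perm, ]
  shuffled[[3]]$meta <- shuffled[[3]]$meta[perm, ]
  fused2 <- fuse(shuffled)
  expect_equal(fused2$X, fused$X)
  empty <- parts[[1]]; empty$X <- empty$X[0, , drop = FALSE]
  empty$meta <- empty$meta[0, ]
  expect_error(fuse(list(parts[[1]], empty)), "alignment")
})

test_that("leave-one-out loss matches brute-force enumeration", {
  set.seed(3)
  for (case in 1:3) {
    n <- sample(4:10, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n); y <- rnorm(n)
    w <- runif(p); sig <- runif(1, 0.5, 2)
    D <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) D[i, j] <- sum(w^2 * abs(X[i, ] - X[j, ]))
    K <- exp(-D / sig); diag(K) <- 0
    G <- K / rowSums(K)
    Li <- vapply(1:n, function(i)
      sum(G[i, -i] * (1 - exp(-abs(y[i] - y[-i])))), numeric(1))
    r <- nca_loo_loss(w, X, y, sigma = sig)
    expect_equal(r$gamma, G, tolerance = 1e-10)
    expect_equal(r$Li, Li, tolerance = 1e-10)
    expect_equal(unname(rowSums(r$gamma)), rep(1, n), tolerance = 1e-12)
  }
})

test_that("degenerate weight and target cases hit the closed forms", {
  X <- rand_matrix(6, 3, 4); y <- rnorm(6)
  r <- nca_loo_loss(rep(0, 3), X, y)
  expect_true(all(abs(r$gamma[row(r$gamma) != col(r$gamma)] - 1 / 5) < 1e-12))
  same <- nca_loo_loss(runif(3), X, rep(4.2, 6))
  expect_equal(same$Li, rep(0, 6))
  expect_error(nca_loo_loss(rep(1, 3), X[1, , drop = FALSE], y[1]), "n < 2")
})

test_that("the objective is linear in lambda and has an exact gradient", {
  X <- rand_matrix(8, 4, 5); y <- rnorm(8); w <- runif(4)
  f1 <- nca_objective(w, X, y, lambda = 0.01)
  f2 <- nca_objective(w, X, y, lambda = 0.02)
  expect_equal(f2 - f1, 0.01 * sum(w^2), tolerance = 1e-12)
  expect_equal(nca_objective(rep(0, 4), X, y, lambda = 5),
               nca_loo_loss(rep(0, 4), X, y)$mean)
  og <- nca_objective(w, X, y, 0.01, gradient = TRUE)
  fd <- vapply(1:4, function(k) {
    h <- 1e-6; wp <- w; wm <- w; wp[k] <- w[k] + h; wm[k] <- w[k] - h
    (nca_objective(wp, X, y, 0.01) - nca_objective(wm, X, y, 0.01)) / (2 * h)
  }, numeric(1))
  expect_equal(og$gradient, fd, tolerance = 1e-5)
})

test_that("fitted weights shrink under heavy regularization and find the signal", {
  set.seed(9)
  n <- 120; X <- matrix(rnorm(n * 21), n)
  y <- X[, 1] + rnorm(n, 0, 0.1)
  s <- rrfuse:::standardize_fit(X)
  Xs <- rrfuse:::standardize_apply(X, s)
  f_big <- suppressWarnings(fit_nca(Xs, y, lambda = 10))
  expect_lt(max(abs(f_big$w)), 0.05)
  f <- suppressWarnings(fit_nca(Xs, y, lambda = 0.001))
  expect_equal(which.max(abs(f$w)), 1L)
  expect_lte(f$objective[["final"]], f$objective[["initial"]])
  f2 <- suppressWarnings(fit_nca(Xs, y, lambda = 0.001))
  expect_identical(f$w, f2$w)
})

test_that("lambda tuning uses the robust loss and prefers large lambda on noise", {
  z <- function(a, b) 1 - exp(-abs(a - b))
  expect_equal(z(3, 3), 0)
  expect_equal(z(0, 50), 1, tolerance = 1e-20)
  X <- rand_matrix(40, 4, 6); y <- rnorm(40)
  one <- tune_lambda(X, y, rnca_config(lambda_grid = 0.005, tune_maxit = 5))
  expect_equal(one$lambda_b, 0.005)
  # pure-noise targets: the selected lambda should sit in the top half of the
  # grid for most seeds
  grid <- 10^seq(-5, -1, length.out = 10)
  picks <- vapply(1:5, function(s) {
    set.seed(s * 11)
    Xn <- matrix(rnorm(60 * 5), 60); yn <- rnorm(60)
    tune_lambda(Xn, yn, rnca_config(lambda_grid = grid, tune_maxit = 10,
                                    seed = s))$lambda_b
  }, numeric(1))
  expect_gte(sum(picks >= grid[6]), 3)
  expect_error(tune_lambda(X[1:3, ], y[1:3], rnca_config()), "fewer samples")
})

test_that("feature selection thresholds on relative weight", {
  w <- structure(list(w = c(1.0, 0.5, 0.05)), class = "nca_weights")
  expect_equal(select_features(w), c(1L, 2L))
  w_eq <- structure(list(w = rep(0.3, 6)), class = "nca_weights")
  expect_equal(select_features(w_eq), 1:6)
  w_z <- structure(list(w = rep(0.2, 15)), class = "nca_weights")
  expect_warning(idx <- select_features(w_z, absolute = 99), "top-10")
  expect_length(idx, 10L)
})

test_that("RNCA keeps planted relevant features in most replicates", {
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    n <- 80; p <- 12
    X <- matrix(rnorm(n * p), n)
    y <- X[, 1] - 0.8 * X[, 2] + 0.6 * X[, 3] + rnorm(n, 0, 0.15)
    w <- suppressWarnings(
      rnca_select(X, y, rnca_config(maxit = 60, seed = s), lambda = 0.001))
    all(1:3 %in% w$selection)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("arithmetic fusion averages aligned predictions", {
  expect_equal(arithmetic_fusion(c(12, 10), c(16, 10), c(14, 10), c(18, 10)),
               c(15, 10))
  p <- runif(5)
  expect_equal(arithmetic_fusion(p, p, p), p)
  expect_error(arithmetic_fusion(1:3, 1:4), "alignment")
  # convexity: AF MAE never exceeds the worst single-family MAE
  set.seed(7)
  y <- runif(50, 8, 25)
  preds <- lapply(1:4, function(i) y + rnorm(50, 0, i / 2))
  af <- arithmetic_fusion(preds)
  expect_lte(mae(y, af), max(vapply(preds, function(p) mae(y, p), numeric(1))))
})
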