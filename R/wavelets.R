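# Wavelet transforms used by the multi-phase feature family: maximal-overlap
# DWT (wavelet variance), full wavelet-packet decomposition (Shannon
# entropies), and decimated detail coefficients for wavelet-leader
# multifractal log-cumulant estimation. Implemented directly because the
# pipeline needs only these three fixed operations.

# Analysis filter pairs (dec_lo, dec_hi), standard orthonormal/biorthogonal
# coefficients, sum(dec_lo) = sqrt(2).
.wavelet_filters <- list(
  sym4 = list(
    lo = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
    hi = c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
           0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
           0.02963552764599851, -0.07576571478927333)),
  db3 = list(
    lo = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
           0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
    hi = c(-0.33267055295008263, 0.8068915093110925, -0.45987750211849154,
           -0.13501102001025458, 0.08544127388202666, 0.03522629188570953)),
  bior3.1 = list(
    lo = c(-0.3535533905932738, 1.0606601717798212, 1.0606601717798212,
           -0.3535533905932738),
    hi = c(-0.1767766952966369, 0.5303300858899106, -0.5303300858899106,
           0.1767766952966369))
)

wavelet_filter <- function(wavelet) {
  f <- .wavelet_filters[[wavelet]]
  if (is.null(f)) stop("unknown wavelet: ", wavelet, call. = FALSE)
  f
}

# circular (periodic) filtering used by the MODWT and wavelet packets
circ_filter_down <- function(x, h) {
  n <- length(x)
  L <- length(h)
  # y[k] = sum_l h[l] x[(2k - l) mod n], standard decimated periodized DWT
  y <- numeric(floor(n / 2))
  for (k in seq_along(y)) {
    idx <- (2 * k - seq_len(L)) %% n + 1L
    y[k] <- sum(h * x[idx])
  }
  y
}

#' Maximal-overlap discrete wavelet transform (MODWT)
#'
#' Shift-invariant, non-decimated pyramid with periodic boundary handling.
#'
#' @param x numeric signal.
#' @param level decomposition depth J.
#' @param wavelet filter name (`"sym4"`, `"db3"`, `"bior3.1"`).
#' @return list with `W` (list of detail coefficient vectors, levels 1..J),
#'   `V` (level-J scaling coefficients), `wavelet`, `level`.
#' @export
modwt <- function(x, level, wavelet = "sym4") {
  f <- wavelet_filter(wavelet)
  ht <- f$hi / sqrt(2); gt <- f$lo / sqrt(2)
  n <- length(x)
  L <- length(ht)
  if (n < L * 2^(level - 1))
    stop("signal too short for requested MODWT level", call. = FALSE)
  W <- vector("list", level)
  V <- x
  for (j in seq_len(level)) {
    step <- 2^(j - 1)
    Wj <- Vj <- numeric(n)
    lags <- (seq_len(L) - 1L) * step
    for (t in seq_len(n)) {
      idx <- (t - 1L - lags) %% n + 1L
      Wj[t] <- sum(ht * V[idx])
      Vj[t] <- sum(gt * V[idx])
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V, wavelet = wavelet, level = level)
}

#' MODWT wavelet variance at one level
#'
#' Unbiased estimator: boundary coefficients affected by circular wrap-around
#' (the first `L_j - 1` of each level, `L_j = (2^j - 1)(L - 1) + 1`) are
#' excluded.
#'
#' @param x numeric signal.
#' @param level scale level j (default 3).
#' @param wavelet filter name.
#' @param unbiased drop boundary coefficients (default `TRUE`).
#' @return scalar wavelet variance.
#' @export
modwt_variance <- function(x, level = 3, wavelet = "sym4", unbiased = TRUE) {
  f <- wavelet_filter(wavelet)
  L <- length(f$lo)
  Lj <- (2^level - 1) * (L - 1) + 1
  if (length(x) < Lj)
    stop("signal too short for MODWT variance at this level", call. = FALSE)
  W <- modwt(x, level, wavelet)$W[[level]]
  if (unbiased) {
    w <- W[Lj:length(W)]
    sum(w^2) / length(w)
  } else mean(W^2)
}

#' Wavelet-packet Shannon entropies
#'
#' Full wavelet-packet decomposition to `level` (2^level terminal nodes in
#' natural filter-bank order); per node the Shannon entropy
#' \eqn{-\sum p_i \log p_i} of the normalized squared coefficients. A node
#' with zero energy has entropy 0 by convention.
#'
#' @param x numeric signal, length >= 2^level.
#' @param level packet depth (default 4, i.e. 16 nodes).
#' @param wavelet filter name.
#' @return numeric vector of length 2^level.
#' @export
wp_entropy <- function(x, level = 4, wavelet = "sym4") {
  if (length(x) < 2^level)
    stop("signal too short for wavelet-packet depth", call. = FALSE)
  f <- wavelet_filter(wavelet)
  nodes <- list(x)
  for (j in seq_len(level)) {
    nxt <- vector("list", 2 * length(nodes))
    for (k in seq_along(nodes)) {
      v <- nodes[[k]]
      if (length(v) %% 2 == 1L) v <- c(v, v[length(v)])  # pad odd nodes
      nxt[[2 * k - 1L]] <- circ_filter_down(v, f$lo)
      nxt[[2 * k]] <- circ_filter_down(v, f$hi)
    }
    nodes <- nxt
  }
  vapply(nodes, function(v) {
    e <- v^2
    tot <- sum(e)
    if (tot <= 0) return(0)
    p <- e[e > 0] / tot
    -sum(p * log(p))
  }, numeric(1))
}

# Decimated detail coefficients per scale with open (valid-only) boundaries,
# L1-normalized (2^{-j/2} factor) as required for Hoelder-exponent scaling.
dwt_details_valid <- function(x, wavelet) {
  f <- wavelet_filter(wavelet)
  L <- length(f$lo)
  details <- list()
  v <- x
  j <- 0L
  while (length(v) >= 2 * L) {
    j <- j + 1L
    nv <- length(v)
    # valid convolution: only coefficients with full filter support
    d <- numeric(0); s <- numeric(0)
    starts <- seq(1L, nv - L + 1L, by = 2L)
    d <- vapply(starts, function(i) sum(f$hi * v[i:(i + L - 1L)]), numeric(1))
    s <- vapply(starts, function(i) sum(f$lo * v[i:(i + L - 1L)]), numeric(1))
    details[[j]] <- d * 2^(-j / 2)
    v <- s
  }
  details
}

#' Multifractal wavelet-leader log-cumulants
#'
#' Wavelet-leader analysis: per scale j the leaders are local suprema of the
#' L1-normalized detail coefficient magnitudes over the dyadic neighborhood
#' (the coefficient, its finer-scale descendants, and its two neighbors).
#' The first two log-cumulants come from weighted least-squares regressions
#' of the mean and variance of log-leaders against j log 2: `c1` estimates
#' the dominant Hoelder exponent, `c2` the multifractality width (c2 <= 0,
#' ~0 for monofractal signals).
#'
#' @param x numeric signal, length >= 64.
#' @param wavelet filter name (default `"db3"`).
#' @return named numeric vector `c(c1, c2)`.
#' @export
mwl_fractal <- function(x, wavelet = "db3") {
  if (length(x) < 64)
    stop("insufficient scales: need at least 64 samples", call. = FALSE)
  details <- dwt_details_valid(x - mean(x), wavelet)
  J <- length(details)
  if (J < 3)
    stop("insufficient scales for leader regression", call. = FALSE)
  # cumulative dyadic maxima: m[[j]][k] = max |d| over scale<=j descendants
  m <- vector("list", J)
  m[[1]] <- abs(details[[1]])
  for (j in 2:J) {
    dj <- abs(details[[j]])
    prev <- m[[j - 1]]
    mj <- dj
    for (k in seq_along(dj)) {
      child <- c(2 * k - 1L, 2 * k)
      child <- child[child <= length(prev)]
      if (length(child)) mj[k] <- max(mj[k], prev[child])
    }
    m[[j]] <- mj
  }
  u <- v <- w <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    mj <- m[[j]]
    nk <- length(mj)
    if (nk < 6) next
    lead <- vapply(seq_len(nk), function(k)
      max(mj[max(1L, k - 1L):min(nk, k + 1L)]), numeric(1))
    lead <- pmax(lead, .Machine$double.xmin)
    ll <- log(lead)
    u[j] <- mean(ll)
    v[j] <- mean((ll - u[j])^2)
    w[j] <- nk
  }
  ok <- which(!is.na(u))
  ok <- ok[ok >= 2]                      # drop the finest scale (noise-dominated)
  if (length(ok) < 3) ok <- which(!is.na(u))
  jj <- ok * log(2)
  wt <- w[ok]
  wls_slope <- function(yv) {
    W <- wt / sum(wt)
    xb <- sum(W * jj); yb <- sum(W * yv)
    sum(W * (jj - xb) * (yv - yb)) / sum(W * (jj - xb)^2)
  }
  c(c1 = wls_slope(u[ok]), c2 = wls_slope(v[ok]))
}
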