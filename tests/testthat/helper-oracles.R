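# Independent oracles used across the suite. These deliberately avoid the
# package's own preprocessing path so they can cross-check it.

# Fractional Gaussian noise by Davies-Harte circulant embedding.
dh_fgn <- function(n, H, seed) {
  set.seed(seed)
  m <- 2 * n
  k <- 0:(m / 2)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g, rev(g[2:(m / 2)]))
  lam <- Re(fft(circ))
  stopifnot(min(lam) > -1e-9)
  lam <- pmax(lam, 0)
  z <- complex(real = rnorm(m), imaginary = rnorm(m))
  Re(fft(sqrt(lam / (2 * m)) * z))[1:n] * sqrt(2)
}

# Fractional Brownian motion sample path (Hurst H).
dh_fbm <- function(n, H, seed) cumsum(dh_fgn(n, H, seed))

# Simple local-maximum beat-peak detector (threshold at the 60% quantile),
# independent of the package's AIMS segmentation.
oracle_beat_peaks <- function(x, fs, min_sep_s = 0.3) {
  thr <- quantile(x, 0.6)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] > thr]
  if (!length(cand)) return(list(times = numeric(0), values = numeric(0)))
  keep <- cand[1]
  for (i in cand[-1]) {
    if ((i - keep[length(keep)]) / fs >= min_sep_s) keep <- c(keep, i)
    else if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
  }
  list(times = (keep - 1) / fs, values = x[keep])
}

# Envelope-FFT RR oracle: beat-peak amplitude series -> uniform 4 Hz grid ->
# zero-padded FFT argmax in the respiratory band, in bpm.
oracle_envelope_rr <- function(record) {
  pk <- oracle_beat_peaks(record$samples, record$fs)
  fs_o <- 4
  grid <- seq(0, length(record$samples) / record$fs - 1 / fs_o, by = 1 / fs_o)
  env <- approx(pk$times, pk$values, xout = grid, rule = 2)$y
  env <- env - mean(env)
  nfft <- 2^ceiling(log2(length(env)) + 2)
  mag <- Mod(fft(c(env, numeric(nfft - length(env)))))[1:(nfft / 2)]
  freq <- (0:(nfft / 2 - 1)) * fs_o / nfft
  band <- freq >= 0.08 & freq <= 0.8
  60 * freq[band][which.max(mag[band])]
}

# Dominant FFT frequency of a short window (one-sided, DC removed).
oracle_peak_freq <- function(x, fs, pad = 8) {
  x <- x - mean(x)
  nfft <- pad * length(x)
  mag <- Mod(fft(c(x, numeric(nfft - length(x)))))[2:(nfft / 2)]
  freq <- (1:(nfft / 2 - 1)) * fs / nfft
  freq[which.max(mag)]
}

# Small standard-normal design helper with fixed seed.
rand_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}
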