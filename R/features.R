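#' Normalized autocorrelation sequence
#'
#' \eqn{\nu_m = \sum_n (x_n-\mu)(x_{n+m}-\mu) / \sum_n (x_n-\mu)^2} for lags
#' m = 0..N-1; the zero-lag value is exactly 1.
#'
#' @param x numeric window (length >= 2, non-constant).
#' @return numeric vector of length `length(x)` (lags 0..N-1).
#' @export
autocorr <- function(x) {
  n <- length(x)
  if (n < 2) stop("autocorrelation needs at least 2 samples", call. = FALSE)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom <= 0)
    stop("degenerate window: constant signal has no autocorrelation",
         call. = FALSE)
  # FFT-based lagged products (biased estimator, normalized by lag-0)
  np <- 2^ceiling(log2(2 * n))
  f <- fft(c(xc, numeric(np - n)))
  r <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / np
  r / r[1]
}

#' Power-spectral feature vector (256 bins over (0, 2.5] Hz)
#'
#' The autocorrelation sequence of a 160-sample (32 s at 5 Hz) window is
#' Hamming-tapered, zero-padded to 512, and Fourier transformed; the
#' magnitudes at one-sided bins 1..256 (bin k maps to k 5/512 Hz) form the
#' feature vector. Bins whose center frequency falls below 0.1 Hz are zeroed
#' so the retained band is 0.1-2.5 Hz while the dimension stays 256.
#'
#' @param nu autocorrelation sequence from [autocorr()] (length 160 at the
#'   default window geometry).
#' @param n_bins number of retained bins (default 256).
#' @param fs sampling rate of the windowed wave (default 5 Hz).
#' @param f_min low-frequency floor in Hz (default 0.1).
#' @return a `ps_feature`: numeric vector length `n_bins` with attribute
#'   `freq_hz` giving the bin-center frequencies.
#' @export
power_spectrum_features <- function(nu, n_bins = 256, fs = 5, f_min = 0.1) {
  nfft <- 2 * n_bins
  if (length(nu) > nfft)
    stop("autocorrelation longer than transform length", call. = FALSE)
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_along(nu) - 1) / (length(nu) - 1))
  padded <- c(nu * ham, numeric(nfft - length(nu)))
  mag <- Mod(fft(padded))[2:(n_bins + 1)]    # drop DC, keep bins 1..n_bins
  freq <- (1:n_bins) * fs / nfft
  mag[freq < f_min] <- 0
  structure(mag, freq_hz = freq, class = "ps_feature")
}

#' Burg autoregressive coefficients
#'
#' Order-4 (by default) AR coefficients by Burg's method; the Burg recursion
#' guarantees reflection-coefficient magnitudes below 1, hence a stable model.
#'
#' @param x numeric signal (length > 2 x order).
#' @param order AR model order (default 4).
#' @return numeric vector of `order` coefficients (predictive convention:
#'   \eqn{x_t = \sum_i a_i x_{t-i} + e_t}).
#' @export
burg_ar <- function(x, order = 4) {
  if (length(x) <= 2 * order)
    stop("signal too short for AR order", call. = FALSE)
  if (var(x) <= 0) stop("degenerate input: constant signal", call. = FALSE)
  fit <- ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  as.numeric(fit$ar)
}

#' Multi-phase feature vector for one window (230 dimensions)
#'
#' The 4000-sample band-filtered 32 s window (125 Hz) is split into 10 equal
#' contiguous sub-segments of 400 samples; per sub-segment the vector
#' concatenates 4 Burg AR coefficients, 16 wavelet-packet Shannon entropies,
#' 2 wavelet-leader log-cumulants, and 1 MODWT wavelet variance. Blocks are
#' ordered by family: AR (40), entropy (160), fractal (20), variance (10).
#'
#' @param window_raw numeric vector, the window's raw band-filtered segment.
#' @param n_sub number of sub-segments (default 10).
#' @param wavelet filter for packets/variance (default `"sym4"`).
#' @param leader_wavelet filter for the leader analysis (default `"db3"`).
#' @param var_level MODWT variance level (default 3).
#' @return an `mf_feature`: named numeric vector of length 230 at defaults.
#' @export
extract_mf <- function(window_raw, n_sub = 10, wavelet = "sym4",
                       leader_wavelet = "db3", var_level = 3) {
  n <- length(window_raw)
  sub_len <- floor(n / n_sub)
  ar_b <- ent_b <- fr_b <- va_b <- NULL
  for (s in seq_len(n_sub)) {
    seg <- window_raw[((s - 1) * sub_len + 1):(s * sub_len)]
    if (var(seg) <= 0)
      stop("degenerate window: constant sub-segment", call. = FALSE)
    ar_b <- c(ar_b, burg_ar(seg, 4))
    ent_b <- c(ent_b, wp_entropy(seg, 4, wavelet))
    fr_b <- c(fr_b, mwl_fractal(seg, leader_wavelet))
    va_b <- c(va_b, modwt_variance(seg, var_level, wavelet))
  }
  out <- c(ar_b, ent_b, fr_b, va_b)
  names(out) <- c(sprintf("ar%02d", seq_along(ar_b)),
                  sprintf("ent%03d", seq_along(ent_b)),
                  sprintf("mwl%02d", seq_along(fr_b)),
                  sprintf("wv%02d", seq_along(va_b)))
  structure(out, class = "mf_feature")
}

#' Power-spectral features for one window
#'
#' Convenience wrapper: autocorrelation of the 5 Hz resampled segment
#' followed by [power_spectrum_features()].
#'
#' @param window_resampled numeric vector (160 samples at defaults).
#' @param n_bins retained spectral bins.
#' @return a `ps_feature` vector.
#' @export
extract_ps <- function(window_resampled, n_bins = 256) {
  power_spectrum_features(autocorr(window_resampled), n_bins = n_bins)
}

#' Assemble a cohort feature matrix
#'
#' Stacks per-window features of one family and one modality across all
#' records of a preprocessed cohort. Rows carry subject id, window index and
#' reference RR for grouped splitting and supervised fitting; degenerate
#' windows are skipped with a message.
#'
#' @param window_sets named list: per subject id, a `window_set` from
#'   [preprocess_record()].
#' @param family `"ps"` or `"mf"`.
#' @param modality label stored with the matrix (`"ppg"` or `"ecg"`).
#' @param ... passed to [extract_ps()] / [extract_mf()].
#' @return an `rr_features` object: list with `X` (matrix rows = windows),
#'   `meta` (data.frame: `subject`, `window`, `rr`), `family`, `modality`.
#' @export
build_feature_matrix <- function(window_sets, family = c("ps", "mf"),
                                 modality = c("ppg", "ecg"), ...) {
  family <- match.arg(family)
  modality <- match.arg(modality)
  rows <- list(); subj <- character(0); win <- integer(0); rr <- numeric(0)
  for (id in names(window_sets)) {
    ws <- window_sets[[id]]
    for (w in seq_along(ws)) {
      feat <- tryCatch({
        if (family == "ps") as.numeric(extract_ps(ws[[w]]$resampled, ...))
        else as.numeric(extract_mf(ws[[w]]$raw, ...))
      }, error = function(e) {
        message("skipping degenerate window ", id, "/", w, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(feat)) next
      rows[[length(rows) + 1L]] <- feat
      subj <- c(subj, id); win <- c(win, w)
      rr <- c(rr, ws[[w]]$reference_rr)
    }
  }
  if (!length(rows)) stop("no usable windows", call. = FALSE)
  dims <- lengths(rows)
  if (length(unique(dims)) != 1L)
    stop("assembly error: inconsistent feature dimensions across windows",
         call. = FALSE)
  X <- do.call(rbind, rows)
  colnames(X) <- paste0(modality, "_", family, sprintf("%03d", seq_len(ncol(X))))
  structure(list(X = X, meta = data.frame(subject = subj, window = win, rr = rr),
                 family = family, modality = modality),
            class = "rr_features")
}

#' Write / read a feature matrix as a delimited table with a JSON sidecar
#'
#' @param features an `rr_features` or `rr_fused` object.
#' @param path output TSV path; the sidecar goes to `<path>.json`.
#' @return `path` invisibly (writer); an `rr_features` (reader).
#' @export
write_features <- function(features, path) {
  d <- cbind(features$meta, as.data.frame(features$X))
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(family = features$family, modality = features$modality,
               n_rows = nrow(features$X), n_cols = ncol(features$X),
               blocks = features$blocks)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta_cols <- c("subject", "window", "rr")
  X <- as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE])
  structure(list(X = X, meta = d[, meta_cols],
                 family = side$family, modality = side$modality,
                 blocks = side$blocks),
            class = "rr_features")
}
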