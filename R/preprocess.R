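#' Kaiser-window FIR filter specification
#'
#' Designs a linear-phase FIR filter with a Kaiser window: 3 dB passband edge
#' at `cutoff_hz`, 60 dB stopband attenuation, and the stated transition
#' width. Filter length follows Kaiser's order formula and is forced odd so
#' the centered filter is exactly zero-phase.
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff_hz cutoff frequency in Hz (3 dB edge).
#' @param fs sampling frequency of the signal the filter will be applied to.
#' @param transition_hz transition bandwidth in Hz (default 5 for lowpass,
#'   0.05 for highpass, matching the pipeline's two filtering stages).
#' @param atten_db stopband attenuation in dB.
#' @return a `filter_spec` with the designed coefficients in `$taps`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff_hz, fs,
                        transition_hz = if (match.arg(kind) == "lowpass") 5 else 0.05,
                        atten_db = 60) {
  kind <- match.arg(kind)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)", call. = FALSE)
  beta <- 0.1102 * (atten_db - 8.7)          # Kaiser beta for A > 50 dB
  dw <- 2 * pi * transition_hz / fs
  n <- ceiling((atten_db - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1               # even order -> odd length, type-I
  taps <- signal::fir1(n, 2 * cutoff_hz / fs,
                       type = if (kind == "lowpass") "low" else "high",
                       window = signal::kaiser(n + 1, beta))
  structure(list(kind = kind, cutoff_hz = cutoff_hz, fs = fs,
                 transition_hz = transition_hz, atten_db = atten_db,
                 taps = as.numeric(taps)),
            class = "filter_spec")
}

# Zero-phase FIR application: centered convolution of the odd-length
# symmetric filter with reflection padding at the edges.
apply_fir <- function(x, taps) {
  m <- length(taps)
  if (length(x) < m)
    stop("signal shorter than filter length", call. = FALSE)
  half <- (m - 1) / 2
  pad_l <- rev(x[seq_len(half) + 1L])                # reflect around x[1]
  pad_r <- rev(x[length(x) - seq_len(half)])         # reflect around x[n]
  xp <- c(2 * x[1] - pad_l, x, 2 * x[length(x)] - pad_r)
  y <- stats::filter(xp, taps, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}

#' Low-pass filter a raw waveform (default 35 Hz cutoff)
#'
#' Removes high-frequency noise before pulse segmentation; zero-phase so
#' fiducial timing is preserved.
#'
#' @param samples numeric waveform.
#' @param fs sampling frequency in Hz.
#' @param spec optional [filter_spec()]; default 35 Hz lowpass at `fs`.
#' @return filtered waveform, same length.
#' @export
lowpass_filter <- function(samples, fs, spec = NULL) {
  if (is.null(spec)) spec <- filter_spec("lowpass", 35, fs)
  apply_fir(samples, spec$taps)
}

#' High-pass filter a resampled wave (default 0.0665 Hz cutoff)
#'
#' Removes baseline drift from the 5 Hz fiducial-amplitude series; the
#' respiratory band (>= 0.1 Hz) passes essentially unchanged.
#'
#' @param wave a `resampled_wave` (see [resample_series()]) or numeric vector.
#' @param fs sampling frequency (taken from the wave when omitted).
#' @param spec optional [filter_spec()]; default 0.0665 Hz highpass.
#' @return same type as `wave`, drift removed.
#' @export
highpass_filter <- function(wave, fs = NULL, spec = NULL) {
  x <- if (inherits(wave, "resampled_wave")) wave$samples else wave
  if (is.null(fs)) fs <- if (inherits(wave, "resampled_wave")) wave$fs_out else
    stop("fs required for plain numeric input", call. = FALSE)
  if (is.null(spec)) spec <- filter_spec("highpass", 0.0665, fs)
  y <- apply_fir(x, spec$taps)
  if (inherits(wave, "resampled_wave")) { wave$samples <- y; wave } else y
}

#' Segment a pulsatile signal into per-beat intervals (AIMS)
#'
#' Adaptive incremental merge segmentation: the signal is cut into short
#' fixed-length line segments classified as up/down/flat by slope, adjacent
#' like-labelled segments are merged, and each up-then-down merged pair is
#' accepted as one cardiac pulse when its amplitude exceeds an adaptive
#' threshold (0.6 x trailing median of candidate amplitudes) and its duration
#' lies within the physiological gate.
#'
#' @param samples band-filtered waveform.
#' @param fs sampling frequency in Hz.
#' @param seg_s elementary line-segment length in seconds (default 40 ms).
#' @param amp_frac amplitude threshold as a fraction of the trailing median
#'   candidate amplitude.
#' @param dur_range acceptable pulse duration in seconds.
#' @param flat_frac slope threshold for the "flat" label, as a fraction of
#'   the median absolute segment rise.
#' @return data.frame with one row per pulse: `start`, `end` (sample
#'   indices, inclusive). Empty (with a warning) when nothing is detected.
#' @export
segment_pulses <- function(samples, fs, seg_s = 0.04, amp_frac = 0.6,
                           dur_range = c(0.25, 1.5), flat_frac = 0.1) {
  n <- length(samples)
  seg_len <- max(2L, round(seg_s * fs))
  n_seg <- floor(n / seg_len)
  if (n_seg < 3L) {
    warning("no detectable pulses: signal too short")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  idx0 <- (seq_len(n_seg) - 1L) * seg_len + 1L
  rises <- samples[idx0 + seg_len - 1L] - samples[idx0]
  eps <- flat_frac * median(abs(rises))
  lab <- ifelse(rises > eps, 1L, ifelse(rises < -eps, -1L, 0L))
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)

  # up run followed by a down run, allowing one short flat run at the
  # rounded peak in between
  cand <- list()
  nr <- length(runs$values)
  for (r in seq_len(nr - 1L)) {
    if (runs$values[r] != 1L) next
    dn <- if (runs$values[r + 1L] == -1L) r + 1L
          else if (runs$values[r + 1L] == 0L && r + 2L <= nr &&
                   runs$values[r + 2L] == -1L) r + 2L
          else next
    s <- idx0[starts[r]]
    e <- min(n, idx0[ends[dn]] + seg_len - 1L)
    cand[[length(cand) + 1L]] <- c(s, e)
  }
  if (!length(cand)) {
    warning("no detectable pulses")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  cand <- do.call(rbind, cand)
  amp <- vapply(seq_len(nrow(cand)), function(i) {
    seg <- samples[cand[i, 1]:cand[i, 2]]
    max(seg) - min(seg)
  }, numeric(1))
  dur <- (cand[, 2] - cand[, 1]) / fs

  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    trail <- amp[max(1L, i - 15L):i]
    thr <- if (length(trail) >= 5L) amp_frac * median(trail)
           else amp_frac * median(amp)
    keep[i] <- amp[i] >= thr && dur[i] >= dur_range[1] && dur[i] <= dur_range[2]
  }
  out <- data.frame(start = cand[keep, 1], end = cand[keep, 2])
  if (!nrow(out)) warning("no detectable pulses")
  out
}

#' Extract per-pulse fiducial points (peaks and troughs)
#'
#' One peak (maximum) and one trough (minimum) per pulse interval, located at
#' the sample of the extremum.
#'
#' @param samples band-filtered waveform.
#' @param fs sampling frequency in Hz.
#' @param pulses data.frame from [segment_pulses()].
#' @return list of two `fiducial_series` (`$peaks`, `$troughs`), each with
#'   `times` (s, strictly increasing), `values`, and `kind`.
#' @export
detect_fiducials <- function(samples, fs, pulses) {
  mk <- function(times, values, kind)
    structure(list(times = times, values = values, kind = kind),
              class = "fiducial_series")
  if (!nrow(pulses))
    return(list(peaks = mk(numeric(0), numeric(0), "peak"),
                troughs = mk(numeric(0), numeric(0), "trough")))
  pk_t <- pk_v <- tr_t <- tr_v <- numeric(nrow(pulses))
  for (i in seq_len(nrow(pulses))) {
    seg <- samples[pulses$start[i]:pulses$end[i]]
    imax <- which.max(seg); imin <- which.min(seg)
    pk_t[i] <- (pulses$start[i] + imax - 2) / fs; pk_v[i] <- seg[imax]
    tr_t[i] <- (pulses$start[i] + imin - 2) / fs; tr_v[i] <- seg[imin]
  }
  list(peaks = mk(pk_t, pk_v, "peak"), troughs = mk(tr_t, tr_v, "trough"))
}

#' Resample an irregular fiducial series onto a uniform 5 Hz grid
#'
#' Linear interpolation of the beat-by-beat (time, value) series onto
#' `[0, duration_s)` at `fs_out`; edges held at the nearest observed value.
#'
#' @param fiducials a `fiducial_series` from [detect_fiducials()].
#' @param fs_out output rate in Hz (default 5).
#' @param duration_s record duration in seconds.
#' @return a `resampled_wave`: list with `samples`, `fs_out`, `kind`.
#' @export
resample_series <- function(fiducials, fs_out = 5, duration_s) {
  if (length(fiducials$times) < 2L)
    stop("cannot resample: fewer than 2 fiducial points", call. = FALSE)
  grid <- seq(0, by = 1 / fs_out, length.out = round(duration_s * fs_out))
  y <- approx(fiducials$times, fiducials$values, xout = grid, rule = 2)$y
  structure(list(samples = y, fs_out = fs_out, kind = fiducials$kind),
            class = "resampled_wave")
}

#' Cut a record into non-overlapping 32 s analysis windows
#'
#' Windows start at t = 0 and any trailing partial window is dropped. Each
#' window carries both the 5 Hz resampled segment (160 samples at defaults)
#' and the aligned band-filtered raw segment (4000 samples at 125 Hz).
#'
#' @param wave a `resampled_wave` (drift-removed 5 Hz fiducial series).
#' @param raw_filtered the band-filtered 125 Hz waveform.
#' @param fs_raw raw sampling rate in Hz.
#' @param win_s window length in seconds.
#' @param reference_rr optional per-window reference RR (bpm).
#' @return a `window_set`: list of windows, each with `resampled` (numeric),
#'   `raw` (numeric), `start_s`, and `reference_rr` (or `NA`).
#' @export
window_signal <- function(wave, raw_filtered, fs_raw = 125, win_s = 32,
                          reference_rr = NULL) {
  fs5 <- wave$fs_out
  dur <- length(wave$samples) / fs5
  n_win <- floor(dur / win_s)
  if (n_win < 1L) {
    warning("record shorter than one window")
    return(structure(list(), class = "window_set"))
  }
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    i5 <- ((w - 1) * win_s * fs5 + 1):(w * win_s * fs5)
    ir <- ((w - 1) * win_s * fs_raw + 1):min(length(raw_filtered), w * win_s * fs_raw)
    out[[w]] <- list(resampled = wave$samples[i5], raw = raw_filtered[ir],
                     start_s = (w - 1) * win_s,
                     reference_rr = if (!is.null(reference_rr) &&
                                        length(reference_rr) >= w)
                       reference_rr[w] else NA_real_)
  }
  structure(out, class = "window_set")
}

#' Reference respiratory rate for one window from breath annotations
#'
#' Per annotation track, RR = 60 / mean inter-breath interval of the breaths
#' falling inside the window; the returned value is the mean over the two
#' tracks. Windows in which any track has fewer than two breaths get `NA`.
#'
#' @param breath_tracks list of numeric vectors of breath times (s).
#' @param start_s,win_s window start and length in seconds.
#' @return RR in bpm, or `NA_real_` when the reference is missing.
#' @export
reference_rr <- function(breath_tracks, start_s, win_s = 32) {
  per_track <- vapply(breath_tracks, function(tt) {
    b <- tt[tt >= start_s & tt < start_s + win_s]
    if (length(b) < 2L) return(NA_real_)
    60 / mean(diff(b))
  }, numeric(1))
  if (anyNA(per_track)) NA_real_ else mean(per_track)
}

#' Preprocess one record end to end
#'
#' Runs the full chain: 35 Hz low-pass, AIMS pulse segmentation (on the
#' absolute signal for ECG), fiducial extraction (peak amplitudes), 5 Hz
#' linear-interpolation resampling, 0.0665 Hz high-pass detrending, and 32 s
#' windowing with reference RR from the record's breath annotations.
#'
#' @param record an `rr_record`.
#' @param win_s window length in seconds.
#' @param fiducial `"peak"` (default) or `"trough"`: which fiducial-amplitude
#'   series feeds the resampled wave.
#' @param dur_range pulse-duration gate passed to [segment_pulses()];
#'   defaults depend on modality (PPG pulses vs narrow QRS complexes).
#' @return a `window_set` (see [window_signal()]).
#' @export
preprocess_record <- function(record, win_s = 32,
                              fiducial = c("peak", "trough"),
                              dur_range = NULL) {
  fiducial <- match.arg(fiducial)
  if (is.null(dur_range))
    dur_range <- if (record$modality == "ecg") c(0.04, 0.5) else c(0.25, 1.5)
  filt <- lowpass_filter(record$samples, record$fs)
  seg_input <- if (record$modality == "ecg") abs(filt) else filt
  pulses <- segment_pulses(seg_input, record$fs, dur_range = dur_range)
  fid <- detect_fiducials(filt, record$fs, pulses)
  series <- if (fiducial == "peak") fid$peaks else fid$troughs
  dur <- length(record$samples) / record$fs
  wave <- resample_series(series, fs_out = 5, duration_s = dur)
  # transition width widens for short records so the detrending filter still
  # fits inside the signal; 400 s records get the 0.05 Hz design
  hp <- filter_spec("highpass", 0.0665, 5, transition_hz = max(0.05, 20 / dur))
  wave <- highpass_filter(wave, spec = hp)
  n_win <- floor(dur / win_s)
  ref <- if (!is.null(record$breath_times)) {
    vapply(seq_len(n_win) - 1L,
           function(w) reference_rr(record$breath_times, w * win_s, win_s),
           numeric(1))
  } else record$true_rr_bpm
  window_signal(wave, filt, fs_raw = record$fs, win_s = win_s,
                reference_rr = ref)
}
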