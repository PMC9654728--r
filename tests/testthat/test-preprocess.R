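test_that("35 Hz lowpass preserves the passband and kills the stopband", {
  fs <- 125
  t <- (0:9999) / fs
  tone <- function(f) sin(2 * pi * f * t)
  mid <- 2000:8000  # avoid edges when measuring gain
  y1 <- lowpass_filter(tone(1), fs)
  expect_equal(sd(y1[mid]) / sd(tone(1)[mid]), 1, tolerance = 0.01)
  y55 <- lowpass_filter(tone(55), fs)
  expect_lt(20 * log10(sd(y55[mid]) / sd(tone(55)[mid])), -20)
  yc <- lowpass_filter(rep(2.5, 2000), fs)
  expect_equal(yc, rep(2.5, 2000), tolerance = 1e-3)
  expect_error(lowpass_filter(rnorm(10), fs), "shorter than filter")
})

test_that("0.0665 Hz highpass removes drift but passes the respiratory band", {
  fs <- 5
  t <- (0:1999) / fs
  expect_lt(max(abs(highpass_filter(rep(3, 2000), fs))), 0.01)
  y <- highpass_filter(sin(2 * pi * 0.25 * t), fs)
  mid <- 400:1600
  expect_equal(sd(y[mid]) / sd(sin(2 * pi * 0.25 * t)[mid]), 1, tolerance = 0.05)
  ramp <- highpass_filter(seq(0, 10, length.out = 2000), fs)
  expect_lt(abs(mean(ramp)), 0.05)
})

test_that("pulse segmentation counts beats at the cardiac rate", {
  cfg <- synth_config(noise_sd = 0, seed = 1)
  n60 <- {
    rec <- generate_ppg(cfg, 3, rr_bpm = 15, hr_bpm = 60)
    nrow(segment_pulses(lowpass_filter(rec$samples[1:7500], 125), 125))
  }
  expect_equal(n60, 60, tolerance = 1 / 60)
  n90 <- {
    rec <- generate_ppg(cfg, 3, rr_bpm = 15, hr_bpm = 90)
    nrow(segment_pulses(lowpass_filter(rec$samples[1:7500], 125), 125))
  }
  expect_equal(n90 / n60, 1.5, tolerance = 0.05)
  expect_warning(p0 <- segment_pulses(rep(0, 5000), 125), "no detectable")
  expect_equal(nrow(p0), 0L)
})

test_that("fiducials sit on the per-pulse extrema", {
  fs <- 125
  t <- (0:499) / fs
  pulse <- exp(-0.5 * ((t - 2) / 0.1)^2)
  fid <- detect_fiducials(pulse, fs, data.frame(start = 1L, end = 500L))
  expect_equal(fid$peaks$times, 2, tolerance = 1 / fs)
  inv <- detect_fiducials(-pulse, fs, data.frame(start = 1L, end = 500L))
  expect_equal(inv$troughs$times, fid$peaks$times)
  expect_equal(inv$troughs$values, -fid$peaks$values)

  rec <- generate_ppg(synth_config(noise_sd = 0, seed = 5), 11,
                      rr_bpm = 18, hr_bpm = 72)
  filt <- lowpass_filter(rec$samples, 125)
  f <- detect_fiducials(filt, 125, segment_pulses(filt, 125))
  beat_peaks <- rec$beat_times + 0.25 * 60 / 72   # systolic offset of template
  offs <- vapply(f$peaks$times, function(tt) min(abs(tt - beat_peaks)), numeric(1))
  expect_lt(max(offs), 0.04)
})

test_that("resampling interpolates linearly onto the 5 Hz grid", {
  fid <- structure(list(times = c(0, 10), values = c(0, 10), kind = "peak"),
                   class = "fiducial_series")
  w <- resample_series(fid, 5, 10)
  expect_length(w$samples, 50L)
  expect_equal(w$samples[26], 5.0)  # t = 5 s
  cfid <- structure(list(times = 0:9, values = rep(2, 10), kind = "peak"),
                    class = "fiducial_series")
  expect_true(all(resample_series(cfid, 5, 10)$samples == 2))
  tb <- seq(0.5, 63.5, by = 0.8)   # beat-spaced samples of a 0.25 Hz envelope
  env <- structure(list(times = tb, values = sin(2 * pi * 0.25 * tb),
                        kind = "peak"), class = "fiducial_series")
  rs <- resample_series(env, 5, 64)
  expect_equal(oracle_peak_freq(rs$samples, 5), 0.25, tolerance = 0.02)
  one <- structure(list(times = 1, values = 1, kind = "peak"),
                   class = "fiducial_series")
  expect_error(resample_series(one, 5, 10), "cannot resample")
})

test_that("windowing follows the floor rule with exact sample counts", {
  mk_wave <- function(dur) structure(list(samples = rnorm(dur * 5), fs_out = 5,
                                          kind = "peak"),
                                     class = "resampled_wave")
  raw <- rnorm(400 * 125)
  expect_length(window_signal(mk_wave(400), raw), 12L)
  expect_length(window_signal(mk_wave(32), raw[1:4000]), 1L)
  expect_length(window_signal(mk_wave(63.8), raw[1:7975]), 1L)
  ws <- window_signal(mk_wave(400), raw)
  expect_true(all(vapply(ws, function(w) length(w$resampled), integer(1)) == 160L))
  expect_true(all(vapply(ws, function(w) length(w$raw), integer(1)) == 4000L))
  expect_warning(window_signal(mk_wave(20), raw[1:2500]), "shorter")
})

test_that("reference RR averages the two annotation tracks", {
  expect_equal(reference_rr(list(seq(0, 32, 4), seq(1, 32, 4)), 0), 15.0)
  expect_equal(reference_rr(list(seq(0, 32, 3), seq(1, 32, 3)), 0), 20.0)
  tr14 <- seq(0, 32, 60 / 14); tr16 <- seq(0, 32, 60 / 16)
  expect_equal(reference_rr(list(tr14, tr16), 0), 15.0)
  expect_true(is.na(reference_rr(list(c(1, 5), 10), 0)))
})

test_that("the preprocessing chain is deterministic and recovers RR per window", {
  rec <- generate_ppg(synth_config(noise_sd = 0, seed = 21), 13,
                      rr_bpm = 15, hr_bpm = 75)
  ws1 <- preprocess_record(rec)
  ws2 <- preprocess_record(rec)
  expect_identical(ws1, ws2)
  expect_length(ws1, 12L)
  for (w in ws1) {
    expect_lt(abs(oracle_peak_freq(w$resampled, 5) - 0.25), 5 / 160)
    expect_equal(w$reference_rr, 15, tolerance = 0.5)
  }
})
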