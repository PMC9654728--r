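#' Configuration for the synthetic dual-signal generator
#'
#' Defines the conditions of a synthetic cohort: 53 records of 400 s sampled
#' at 125 Hz by default, one PPG and one ECG waveform per subject, with
#' respiration at a fixed per-subject rate driving amplitude, frequency and
#' baseline modulation of the cardiac pulse train.
#'
#' @param n_records number of subjects in the cohort.
#' @param duration_s record length in seconds.
#' @param fs sampling frequency in Hz.
#' @param rr_range respiratory-rate range (bpm) subjects are drawn from.
#' @param hr_range heart-rate range (bpm) subjects are drawn from.
#' @param am_depth amplitude-modulation depth in [0, 1] (fraction of pulse
#'   amplitude swung by respiration).
#' @param fm_depth frequency-modulation depth in [0, 1] (fractional swing of
#'   the instantaneous beat rate).
#' @param bw_depth baseline-wander depth in [0, 1] (respiratory baseline
#'   amplitude relative to unit pulse amplitude).
#' @param noise_sd standard deviation of additive Gaussian noise (signal units).
#' @param seed cohort master seed; all randomness derives from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_records = 53L, duration_s = 400, fs = 125,
                         rr_range = c(8, 25), hr_range = c(55, 95),
                         am_depth = 0.3, fm_depth = 0.05, bw_depth = 0.2,
                         noise_sd = 0.02, seed = 1L) {
  cfg <- list(n_records = as.integer(n_records), duration_s = duration_s,
              fs = fs, rr_range = rr_range, hr_range = hr_range,
              am_depth = am_depth, fm_depth = fm_depth, bw_depth = bw_depth,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  num <- unlist(cfg[c("n_records", "duration_s", "fs", "rr_range", "hr_range",
                      "am_depth", "fm_depth", "bw_depth", "noise_sd", "seed")])
  if (any(!is.finite(num)))
    stop("invalid configuration: non-finite values", call. = FALSE)
  if (cfg$n_records < 1L) stop("invalid configuration: n_records < 1", call. = FALSE)
  if (cfg$duration_s <= 0 || cfg$fs <= 0)
    stop("invalid configuration: duration_s and fs must be positive", call. = FALSE)
  if (cfg$rr_range[1] <= 0 || cfg$rr_range[2] >= 60 ||
      cfg$rr_range[1] > cfg$rr_range[2])
    stop("invalid configuration: rr_range must lie within (0, 60) bpm", call. = FALSE)
  # cardiac band must sit strictly above the respiratory band in Hz
  if (cfg$hr_range[1] / 60 <= cfg$rr_range[2] / 60)
    stop("invalid configuration: hr_range must be above rr_range", call. = FALSE)
  depths <- c(cfg$am_depth, cfg$fm_depth, cfg$bw_depth)
  if (any(depths < 0 | depths > 1))
    stop("invalid configuration: modulation depths must be in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("invalid configuration: noise_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

# Deterministic per-subject seed derived from the cohort seed; kept below 2^31.
derive_seed <- function(seed, i, salt = 0L) {
  (as.numeric(seed) * 2654435L + i * 97561L + salt * 7919L) %% 2147483647
}

# Beat times for one record: t_{n+1} = t_n + 60 / instantaneous HR, where the
# instantaneous beat rate is modulated by respiration (respiratory sinus
# arrhythmia analogue).
beat_times <- function(duration_s, hr_bpm, rr_bpm, fm_depth, t0 = 0) {
  fr <- rr_bpm / 60
  times <- numeric(ceiling(duration_s * hr_bpm / 60) + 16L)
  t <- t0; n <- 0L
  while (t < duration_s + 2) {  # overshoot so edge beats contribute tails
    n <- n + 1L
    times[n] <- t
    inst_hr <- hr_bpm * (1 + fm_depth * sin(2 * pi * fr * t))
    t <- t + 60 / inst_hr
  }
  times[seq_len(n)]
}

# Render a train of per-beat templates onto the sampling grid.
# template_fn(t_rel, width) must return the beat waveform for t_rel in seconds
# relative to beat onset; width is the current beat period.
render_beats <- function(t, beats, amps, widths, template_fn) {
  x <- numeric(length(t))
  fs <- 1 / (t[2] - t[1])
  for (b in seq_along(beats)) {
    lo <- max(1L, floor((beats[b] - 0.05) * fs) + 1L)
    hi <- min(length(t), ceiling((beats[b] + widths[b]) * fs) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] + amps[b] * template_fn(t[idx] - beats[b], widths[b])
  }
  x
}

# PPG beat: systolic upstroke plus a smaller dicrotic (reflected) wave,
# each a Gaussian bump, widths scaled with the beat period.
ppg_template <- function(t_rel, width) {
  exp(-0.5 * ((t_rel - 0.25 * width) / (0.10 * width))^2) +
    0.35 * exp(-0.5 * ((t_rel - 0.55 * width) / (0.12 * width))^2)
}

# ECG beat: single narrow R-wave spike.
ecg_template <- function(t_rel, width) {
  exp(-0.5 * ((t_rel - 0.5 * width) / 0.022)^2)
}

generate_waveform <- function(config, subject_seed, rr_bpm, hr_bpm, modality,
                              subject_id) {
  set.seed(as.integer(subject_seed %% 2147483647))
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  fr <- rr_bpm / 60
  beats <- beat_times(config$duration_s, hr_bpm, rr_bpm, config$fm_depth)
  widths <- c(diff(beats), 60 / hr_bpm)
  amps <- 1 + config$am_depth * sin(2 * pi * fr * beats)
  template <- if (modality == "ppg") ppg_template else ecg_template
  x <- render_beats(t, beats, amps, widths, template)
  x <- x + config$bw_depth * sin(2 * pi * fr * t)
  if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd)

  # two breath-annotation tracks; the second jittered by <= 0.2 s
  period <- 60 / rr_bpm
  track1 <- seq(period / 2, config$duration_s, by = period)
  track2 <- sort(track1 + runif(length(track1), -0.2, 0.2))
  n_win <- floor(config$duration_s / 32)

  structure(list(samples = x, fs = config$fs, modality = modality,
                 subject_id = subject_id,
                 breath_times = list(track1, track2),
                 true_rr_bpm = rep(rr_bpm, n_win),
                 rr_bpm = rr_bpm, hr_bpm = hr_bpm,
                 beat_times = beats[beats < config$duration_s],
                 beat_amps = amps[beats < config$duration_s]),
            class = "rr_record")
}

#' Generate a synthetic PPG record
#'
#' Builds a pulse train of smooth two-Gaussian beats (systolic + dicrotic) at
#' a subject-specific heart rate, with respiration at `rr_bpm` modulating beat
#' amplitude (`am_depth`), instantaneous beat rate (`fm_depth`) and baseline
#' (`bw_depth`), plus additive Gaussian noise. Deterministic given the seeds.
#'
#' @param config a [synth_config()].
#' @param subject_seed integer seed for this subject's randomness.
#' @param rr_bpm,hr_bpm respiratory and heart rate; drawn from the configured
#'   ranges when `NULL`.
#' @param subject_id subject identifier string.
#' @return an `rr_record`: list with `samples`, `fs`, `modality`,
#'   `subject_id`, two `breath_times` annotation tracks, per-window
#'   `true_rr_bpm`, and generator ground truth (`beat_times`, `beat_amps`).
#' @export
generate_ppg <- function(config, subject_seed, rr_bpm = NULL, hr_bpm = NULL,
                         subject_id = "s01") {
  validate_synth_config(config)
  set.seed(as.integer(subject_seed %% 2147483647))
  if (is.null(rr_bpm)) rr_bpm <- runif(1, config$rr_range[1], config$rr_range[2])
  if (is.null(hr_bpm)) hr_bpm <- runif(1, config$hr_range[1], config$hr_range[2])
  generate_waveform(config, subject_seed, rr_bpm, hr_bpm, "ppg", subject_id)
}

#' Generate a synthetic ECG record
#'
#' As [generate_ppg()] but with a narrow QRS-like Gaussian spike per beat.
#' @inheritParams generate_ppg
#' @return an `rr_record`.
#' @export
generate_ecg <- function(config, subject_seed, rr_bpm = NULL, hr_bpm = NULL,
                         subject_id = "s01") {
  validate_synth_config(config)
  set.seed(as.integer(subject_seed %% 2147483647))
  if (is.null(rr_bpm)) rr_bpm <- runif(1, config$rr_range[1], config$rr_range[2])
  if (is.null(hr_bpm)) hr_bpm <- runif(1, config$hr_range[1], config$hr_range[2])
  generate_waveform(config, subject_seed, rr_bpm, hr_bpm, "ecg", subject_id)
}

#' Generate a synthetic cohort of paired PPG and ECG records
#'
#' Draws per-subject respiratory and heart rates from the configured ranges
#' using the cohort seed; the PPG and ECG of a subject share the same
#' respiratory trajectory and breath annotations.
#'
#' @param config a [synth_config()].
#' @param rr_bpm optional fixed respiratory rate (bpm) applied to every
#'   subject, overriding the random draw.
#' @return list of `n_records` elements, each `list(ppg =, ecg =)` of
#'   `rr_record` objects.
#' @export
generate_cohort <- function(config, rr_bpm = NULL) {
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_records
  rr <- if (is.null(rr_bpm)) runif(n, config$rr_range[1], config$rr_range[2])
        else rep(rr_bpm, n)
  hr <- runif(n, config$hr_range[1], config$hr_range[2])
  lapply(seq_len(n), function(i) {
    id <- sprintf("s%02d", i)
    ppg <- generate_waveform(config, derive_seed(config$seed, i, 1L),
                             rr[i], hr[i], "ppg", id)
    ecg <- generate_waveform(config, derive_seed(config$seed, i, 1L),
                             rr[i], hr[i], "ecg", id)
    list(ppg = ppg, ecg = ecg)
  })
}

#' Write a record as delimited text (time, amplitude)
#'
#' @param record an `rr_record`.
#' @param path output file path; tab-separated, two columns (`time_s`,
#'   `amplitude`), plus one annotation file per breath track
#'   (`<path>.breaths1.txt`, `<path>.breaths2.txt`) when annotations exist.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  t <- (seq_along(record$samples) - 1) / record$fs
  write.table(data.frame(time_s = t, amplitude = record$samples), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(record$breath_times)) {
    for (k in seq_along(record$breath_times)) {
      writeLines(format(record$breath_times[[k]], digits = 10),
                 sprintf("%s.breaths%d.txt", path, k))
    }
  }
  invisible(path)
}

#' Read a record from delimited text
#'
#' @param path file written by [write_record()] (or any two-column delimited
#'   text with time in seconds and amplitude).
#' @param modality `"ppg"` or `"ecg"`.
#' @param subject_id subject identifier.
#' @return an `rr_record`.
#' @export
read_record <- function(path, modality = c("ppg", "ecg"), subject_id = "s01") {
  modality <- match.arg(modality)
  d <- read.table(path, header = TRUE, sep = "\t")
  fs <- 1 / mean(diff(d[[1]]))
  breath_files <- sprintf("%s.breaths%d.txt", path, 1:2)
  breaths <- NULL
  if (all(file.exists(breath_files)))
    breaths <- lapply(breath_files, function(f) as.numeric(readLines(f)))
  structure(list(samples = d[[2]], fs = round(fs, 6), modality = modality,
                 subject_id = subject_id, breath_times = breaths,
                 true_rr_bpm = NULL),
            class = "rr_record")
}

#' Write a cohort to a directory with a JSON manifest
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(pair) {
    id <- pair$ppg$subject_id
    files <- c(ppg = file.path(dir, paste0(id, "_ppg.txt")),
               ecg = file.path(dir, paste0(id, "_ecg.txt")))
    write_record(pair$ppg, files[["ppg"]])
    write_record(pair$ecg, files[["ecg"]])
    list(subject_id = id, ppg = files[["ppg"]], ecg = files[["ecg"]],
         true_rr_bpm = pair$ppg$true_rr_bpm)
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
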