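---
title: "Respiratory-rate estimation with hybrid features, weighted fusion and exact GP regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-rate estimation with hybrid features, weighted fusion and exact GP regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrfuse)
```

## The problem

Respiration leaves three fingerprints on cardiac waveforms: it modulates the
amplitude of each pulse, the instantaneous beat rate (respiratory sinus
arrhythmia), and the baseline. `rrfuse` estimates respiratory rate (RR, in
breaths per minute) from PPG and ECG records by turning those fingerprints
into feature vectors per 32 s window, learning which features matter, and
regressing RR on them with a model that also quantifies its own uncertainty.
The target users are researchers working with bedside-monitor waveforms
(125 Hz, several-minute records) who need per-window RR estimates with
calibrated 95% intervals rather than point estimates alone.

## Pipeline overview

1. **Preprocessing.** A zero-phase Kaiser-window FIR lowpass (35 Hz cutoff,
   60 dB stopband, 5 Hz transition) removes high-frequency noise. Pulses are
   segmented by adaptive incremental merge segmentation (AIMS): the signal is
   cut into 40 ms line segments labelled up/down/flat by slope, like-labelled
   runs are merged, and each up-then-down pair is accepted as one beat when
   its amplitude exceeds 0.6 times the trailing median candidate amplitude and
   its duration is physiologically plausible. One peak and one trough per
   pulse become fiducial series; the peak-amplitude series is linearly
   interpolated onto a uniform 5 Hz grid, detrended by a 0.0665 Hz Kaiser
   highpass, and cut into non-overlapping 32 s windows (160 samples at 5 Hz,
   aligned with 4000 raw samples at 125 Hz). Reference RR per window is the
   mean over two breath-annotation tracks of 60 / (mean inter-breath
   interval).

2. **Power-spectral (PS) features, 256 per window.** The window's normalized
   autocorrelation (lag-0 value exactly 1) is Hamming-tapered, zero-padded to
   512 and Fourier-transformed; one-sided bins 1–256 cover (0, 2.5] Hz and
   bins below 0.1 Hz are zeroed so the retained band is the respiratory and
   cardiac range while the dimension stays fixed.

3. **Multi-phase (MF) features, 230 per window.** The 4000-sample raw window
   is split into 10 sub-segments of 400 samples; each contributes 4 Burg AR
   coefficients, 16 wavelet-packet Shannon entropies (level-4 packets),
   2 multifractal wavelet-leader log-cumulants, and 1 MODWT wavelet variance
   (level 3), concatenated family-wise into 40 + 160 + 20 + 10 dimensions.

4. **Fusion and selection.** The four families (PPG-PS, PPG-MF, ECG-PS,
   ECG-MF) are concatenated by (subject, window) key into a 972-column
   matrix. Robust neighborhood component analysis (RNCA) learns nonnegative
   per-feature relevance: with weighted L1 distances
   $D_w(x_i,x_j)=\sum_k w_k^2 |x_{ik}-x_{jk}|$ and kernel $e^{-z/\sigma}$,
   each sample stochastically picks a reference neighbour, and the expected
   leave-one-out loss $\frac1n\sum_i\sum_{j\ne i}\gamma_{ij}\,
   \zeta(y_i,y_j)+\lambda\sum_k w_k^2$ is minimized by L-BFGS. The loss
   $\zeta(a,b)=1-e^{-|a-b|}$ is bounded, so outlying windows cannot dominate.
   $\lambda$ is tuned on a 10-point log grid in $[10^{-5},10^{-1}]$ by 5-fold
   cross-validation; features with $|w_k| \ge 0.1\max|w|$ are retained.

5. **Exact GP regression (EGPR).** RR is modelled as
   $y=\theta(x)^\top w+f(x)+\varepsilon$ with a squared-exponential kernel
   $\sigma_f^2\exp(-\|x-x'\|^2/2\eta^2)$ and noise variance $\sigma^2$. The
   basis coefficients are profiled out by generalized least squares and
   $(\eta,\sigma_f^2,\sigma^2)$ maximize the log marginal likelihood by
   L-BFGS in log-parameter space with analytic gradients. Predictions return
   the posterior mean and the predictive interval mean $\pm$ 1.96 sd.

6. **Evaluation.** Repeated 80/20 splits grouped by subject (no subject in
   both train and test), MAE mean and SD across repetitions, CI summaries,
   and one-way ANOVA with Tukey–Kramer comparisons across model variants.
   Arithmetic fusion (AF) — the mean of the four single-family model
   predictions — is the baseline that feature fusion (FF) is compared to.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the study conditions the pipeline was designed
around: 53 subjects, 400 s records at 125 Hz (50,000 samples), per-subject
RR drawn from 8–25 bpm and heart rate from 55–95 bpm, two breath-annotation
tracks (the second jittered by up to 0.2 s), and a pulse train with
respiratory amplitude, frequency and baseline modulation. Defaults are
`am_depth = 0.3`, `fm_depth = 0.05`, `bw_depth = 0.2`, `noise_sd = 0.02`:
amplitude modulation around 30% of pulse height with mild rate modulation is
a realistic mid-range for adult monitoring data, and the noise floor is
small relative to unit pulse amplitude. The PPG beat is a two-Gaussian
(systolic + dicrotic) template and the ECG beat a narrow Gaussian spike,
each scaled with the beat period.

The generator deliberately omits motion artifacts, arrhythmia, waveform
morphology drift, sensor-specific noise colour, and within-record RR
variation (each subject breathes at a fixed rate). Passing tests on this
cohort therefore demonstrate that the pipeline's machinery is correct and
recovers known modulation; they do not establish clinical accuracy on real
intensive-care waveforms, where reference annotation quality and artifact
handling dominate.

## Numerical and design choices

- **Zero-phase filtering.** The odd-length symmetric FIR is applied as a
  single centered convolution with reflection padding; linear phase makes
  this exactly zero-phase, preserving fiducial timing, and behaves robustly
  for the long (365-tap) detrending filter. For records much shorter than
  400 s, the highpass transition width widens (`max(0.05, 20/duration)` Hz)
  so the filter still fits inside the record.
- **Hamming taper.** The taper is applied once, to the autocorrelation
  sequence before its Fourier transform. Tapering the window itself as well
  would smear the spectral peak twice for no benefit.
- **Pulse-duration gates.** PPG pulses must last 0.25–1.5 s, ECG (QRS)
  complexes 0.04–0.5 s; both are configurable. The lower PPG bound admits
  clean pulses up to the top of the configured heart-rate range, where the
  systolic upstroke-plus-downstroke spans about 0.27 s.
- **Wavelet defaults.** sym4 for packets and MODWT variance (level 3);
  daubechies-3 for the wavelet leaders. A short biorthogonal spline filter is
  available, but with only one analysis vanishing moment it biases the
  leader log-cumulant slopes; db3's three vanishing moments estimate the
  Hölder exponent of fractional-Brownian test paths within 0.1, which is the
  accuracy the suite asserts. Packet entropies use natural log; nodes of a
  400-sample sub-segment hold 25 coefficients, so entropies lie in
  [0, log 25].
- **NCA optimization.** The objective is smooth in $w$ (the absolute values
  act on the data, not the weights), so analytic gradients are exact; the
  all-ones start is the conventional uninformative initialization, and the
  O(n²p) objective/gradient kernel is implemented in C++. $\sigma = 1$ on
  standardized features. Standardization constants are always learned on
  training rows only.
- **EGPR numerics.** Cholesky with escalating jitter (1e-10 to 1e-6 of the
  mean diagonal); optimization in log space bounded away from degenerate
  scales; initialization at the median pairwise distance (length scale),
  var(y) (signal variance) and 0.1 var(y) (noise). Targets are centered and
  scaled internally and results mapped back to bpm. The predictive variance
  includes the explicit-basis correction term by default and is floored at
  the noise variance. The kernel prefactor (signal variance) and the
  observation noise are distinct parameters: the marginal-likelihood and
  prediction equations require both, even though a single symbol sometimes
  does double duty in compact notation.
- **Constant basis.** The explicit mean basis defaults to an intercept; a
  linear basis is available. With standardized targets the intercept absorbs
  the cohort mean RR, and predictions far from training data revert to it.
- **Lambda tuning scope.** Cross-validated $\lambda$ tuning is a
  dataset-level setting: the evaluation harness tunes once on the first
  split's training subjects and reuses the tuned value in later repetitions
  rather than re-running the 50 cross-validation fits per repetition.
- **Degenerate inputs.** Constant windows (zero variance) cannot be
  autocorrelated or AR-modelled; they are excluded from feature matrices
  with a logged reason rather than imputed. All-zero wavelet-packet nodes
  have entropy 0 by convention. ANOVA on all-identical groups reports F = 0.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the full 53-record cohort for
structural accounting and the end-to-end comparison, a single evaluation
split (three in the acceptance script) rather than 30 repetitions, 20
simulated GP draws of n = 400 for hyperparameter recovery, 50 planted-feature
replicates for RNCA recovery, and 300/200 train/test points for interval
calibration. These sizes were chosen to exercise every claim at meaningful
scale while keeping a full run in minutes; the harness itself defaults to 30
repetitions for study-scale use.

## Known limitations

- Feature extraction assumes the pulse detector finds essentially every
  beat; heavily corrupted segments should be excluded upstream, as the
  package ships no signal-quality index.
- The wavelet-leader estimator uses valid-support decimated coefficients
  with approximate parent alignment at block edges; fine for 400-sample
  sub-segment features, not intended as a general-purpose multifractal
  toolbox.
- Exact GP inference is O(n³); cohorts beyond a few thousand windows would
  need an approximate GP, which is out of scope.
- The RNCA soft-neighbour loss with $\sigma = 1$ on 972 standardized
  dimensions concentrates on nearest neighbours; this matches its role as a
  relevance learner, but the learned weights are not a posterior over
  feature importance.
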