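---
title: "Methods: window-level freezing-of-gait recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-level freezing-of-gait recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Freezing of gait (FoG) is a transient inability of a Parkinson's patient to
initiate or continue stepping. Clinically it is scored from video, which is
slow and subjective; the goal here is window-level recognition of FoG from
lower-body wearables: an IMU (triaxial accelerometer + gyroscope) at the
waist, both thighs, both shanks and both feet, plus three force-sensing
resistors (FSR) per insole — 48 channels at 100 Hz.

The physiological signature the pipeline exploits is spectral: normal
locomotion concentrates power in a low "motion" band (roughly the step
frequency and its first harmonic), while trembling-type freezing shifts
power into a higher "freezing" band. The freeze index
$$\mathrm{FI} = \frac{P_{[3,8]\,\mathrm{Hz}}}{P_{[0.5,3)\,\mathrm{Hz}}}$$
is the canonical single-number summary of that shift; twelve further
time-domain and statistical features per channel round out the description.

## Pipeline

`simulate/load → interpolate → band-pass → window → featurise →
(per fold) normalise → rank → select top-k → SMOTE → random forest → LOSO`.

Each stage is an exported function; `run_pipeline()` composes them.
Evaluation is leave-one-subject-out (LOSO): one fold per subject, so no
subject contributes windows to both training and test. Everything that can
learn from data — the min–max normaliser, the feature ranking, SMOTE, the
forest — is fit inside the training fold only. Fitting the normaliser or
ranking features on the pooled data would leak test information; the
per-fold discipline costs a little statistical efficiency and buys an
honest estimate.

## The synthetic cohort generator

No public recordings exist for this setting, so the package ships a
generator (`simulate_cohort()`) whose defaults are the study conditions the
analysis assumes:

* 12 subjects, 10 of them freezers; 100 Hz; 755 s per subject
  (about 2.5 h of cohort signal).
* Walking: a locomotor sinusoid with subject-specific fundamental drawn
  from 1.5–2.5 Hz plus a 0.3-amplitude harmonic at twice that frequency, on
  every IMU channel; FSRs carry a half-rectified periodic loading pattern.
* FoG episodes: truncated-lognormal durations with `meanlog = 1.672`,
  `sdlog = 0.917`, truncated to 0.9–76.9 s. These give mean 8.1 s,
  sd 9.3 s and a median of 5.3 s (more than half of episodes under 6 s).
  Episodes arrive at 2.2 per minute among freezers with exponential
  (memoryless) walking gaps — the simplest defensible placement given that
  freezing strikes at walking onset and turns without a known schedule.
  During an episode the locomotor component is attenuated to 0.3 of its
  amplitude and a trembling sinusoid (4–7 Hz, one frequency per episode, 0.8
  of the site's locomotor amplitude) is added; FSR load goes near-constant
  (feet planted).
* Site amplitudes are largest on the shanks (1.0), then thighs (0.9), feet
  (0.7) and waist (0.5), in units of g (accelerometer), dps × 100
  (gyroscope) and load units (FSR); axes are scaled 1/0.7/0.5. Additive
  Gaussian noise has sd 0.05 of each sensor's unit scale. None of these
  amplitudes is reported for real hardware; they are free parameters chosen
  once so that leg channels carry the strongest, cleanly separated signal,
  and they are exposed in `generator_config()`.
* Dropouts: Poisson-arriving masked runs (0.02 gaps/s, 5–50 samples),
  never touching a channel's first or last sample, so interpolation is
  always interior.

Everything is a pure function of `(seed, subject_index)`.

What the generator does *not* emulate: biomechanical gait (no kinematic
chain, no turning context), medication state, sensor quantisation, and the
gradual, irregular onset of real freezing — its episodes switch on and off
abruptly. Passing the recovery tests therefore shows that the pipeline's
machinery (windowing, features, selection, balancing, LOSO bookkeeping) can
extract a planted, spectrally separable signal; it does not certify
clinical performance on real patients.

## Preprocessing

Missing samples are filled by linear interpolation between nearest observed
neighbours (nearest-value extension at the ends). The band-pass filter is a
27-tap (order 26) linear-phase FIR over 0.5–10 Hz, applied in one causal
pass; its constant 13-sample group delay is identical across channels, so
relative window alignment is unaffected. A forward–backward (zero-phase)
pass was rejected because it doubles the effective order and closes the
door on online use.

A 27-tap filter at 100 Hz has an intrinsic resolution of ~3.7 Hz, so a
sharp 0.5 Hz cut-off is not achievable, and strong DC rejection and a flat
low passband edge are *jointly* unachievable: the true minimax (equiripple)
design over stop/pass bands at these edges has deviation ≈ 0.41, i.e.
either the DC gain stays above −10 dB or the passband ripples beyond
±3 dB. The package resolves the trade-off in favour of the filter's stated
purpose, baseline-drift elimination: `design_fir(100)` achieves DC ≤
−20 dB, ±3 dB flatness over 2.5–8 Hz (the trembling band and the upper
locomotor band), and ≤ −10 dB above 15 Hz, accepting attenuation below
~2 Hz. Step fundamentals near 1.5 Hz are attenuated to ~0.4 gain, which
rescales the motion-band denominator of FI identically for every window and
therefore does not disturb the FoG/walk contrast. The fit itself is a
weighted-Chebyshev approximation on the type-I cosine basis via
Lawson-iterated least squares (deterministic, a fixed 1500 iterations);
the achieved weighted minimax and all band edges/weights are recorded in
`design_meta`.

## Windowing and features

Windows are 2 s long, stepped by 0.5 s; the count for `l` samples at `f` Hz
is `floor((l/f − m)/t) + 1`. A window is labelled FoG iff its *start* time
falls inside an annotated episode (half-open `[start, end)`): annotated
onsets lag physiological onsets, so the start-time rule biases labels
toward the earliest evidence. 2 s is long enough for a full step at
1.5–2.5 Hz and gives 0.5 Hz spectral resolution, which separates the 3 Hz
band boundary cleanly.

Per window and channel, 13 features: FI, DFT energy, sum power
(freeze + motion zone), mean, absolute mean, zero-crossing rate, standard
deviation, range, RMS, maximum, minimum, principal-direction eigenvalue and
histogram entropy. Numerical conventions, chosen once:

* Spectra are plain DFTs of the raw 200-sample window — no taper, no
  detrending; the DC bin belongs to neither zone. Band power sums both
  spectral half-planes and divides by the window length, so that power over
  `(0, f/2]` plus the DC term equals `sum(x^2)` (Parseval).
* The printed band boundaries overlap at 3 Hz; 3 Hz is assigned to the
  freezing zone only, so the two zones partition the spectrum and sum power
  counts each bin once.
* FI's denominator is guarded by `1e-12`; a window with no motion-band
  power gets a huge but finite FI.
* Zero crossings are strict sign changes; an exact zero inherits the
  previous nonzero sign, so a flat touch of zero is not counted twice.
* The eigenvalue feature is computed from a sensor's within-window
  covariance across its axes (3×3 for an IMU triplet, scalar variance for
  an FSR), eigenvalues sorted descending and assigned to axes x, y, z — each
  axis column carries one eigenvalue, keeping exactly 13 features per
  channel. Closed-form symmetric 2×2/3×3 eigensolvers keep this vectorised.
* Entropy uses 16 equal-width bins spanning the window's own min–max,
  natural log, `0·log 0 := 0`; a constant window has entropy 0 (and sd,
  range 0; its histogram occupies a single bin).

Full montage: 48 × 13 = 624 features. Min–max normalisation maps each
feature's *training* min/max to 0/1; a training-constant feature maps to 0
everywhere; test values may leave `[0, 1]` and are deliberately not
clipped (clipping would discard the information that a test subject
exceeds the training range).

## Feature ranking

Two filter criteria, computed per feature against the binary label:

* **ANOVA F**: `[SS_b/(M−1)] / [SS_w/(N−M)]` with the textbook
  within-class sum of squares. `SS_w = 0` yields `+Inf`, ranked above all
  finite scores.
* **Mutual information**: plug-in `I = H(Y) − H(Y|X)` (nats) after
  10-quantile binning of the feature. Quantile bins make the estimate
  invariant to monotone transformations and robust to outliers; the bin
  count is exposed (`n_bins`) because the plug-in estimate's bias grows
  with bins/sample ratio.

Ties are broken by column order, making rankings deterministic. Sweeps over
top-k (`topk_sweep()`) report pooled metrics plus fold-wise mean ± sd.

## Class balance

FoG windows are a minority (~25% at the generator defaults). Training folds
are rebalanced to 1:1 by SMOTE: each minority window's 5 nearest minority
neighbours (Euclidean, on normalised features — hence SMOTE runs after
normalisation, so no raw-scale feature dominates the metric) define
segments on which synthetic rows are drawn uniformly. When the required
count is not a multiple of the minority size, remainder parents are drawn
without replacement. Synthetic rows inherit their parent's subject id, so
the leakage audit ("no training row descends from the held-out subject")
remains provable after balancing. Test rows are never balanced.
If a minority class has ≤ 5 members, the neighbour count falls back to
minority − 1 with a warning rather than failing the fold.

## Classifier and evaluation

A 10-tree random forest of fully grown (unpruned) trees, bootstrap
resampling, `sqrt(p)` feature subsampling, majority vote; an exact 5–5 vote
tie is resolved toward the FoG class (the conservative direction for a
screening tool, and deterministic — random tie-breaking would make repeated
runs disagree). The implementation is `ranger`, single-threaded and seeded.

Metrics: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy,
precision `TP/(TP+FP)` and the F-score (harmonic mean of sensitivity and
precision). The primary aggregate is computed from *pooled* confusion
counts across folds, which remains well-defined when a fold has no FoG
windows at all (the two non-freezers); fold-wise means ± sd are also
reported, with a fold excluded from a metric's mean when that metric is
undefined for it (e.g. sensitivity of a non-freezer fold). Sensor-subset
comparisons (`evaluate_sensor_subsets()`) rerun the identical pipeline per
channel subset with shared folds and seeds.

## Reproducibility and problem sizes

One master seed drives everything; per-subject, per-fold and per-stage
seeds are derived from it by a fixed integer hash, so any stage can be
rerun in isolation. The package's own test suite exercises the full
pipeline at the default cohort scale (12 × 755 s) for the
parameter-recovery checks, and smaller cohorts (3–6 subjects, 60–300 s) for
structural and property checks — sizes chosen to keep the whole suite a
few minutes long while leaving the default conditions untouched.

## Known limitations

* The generator's rectangular episode envelopes make boundary windows the
  dominant error source; real FoG onsets are gradual and harder.
* Episode *detection latency* and event-level metrics are out of scope;
  everything is window-level.
* The MI/ANOVA comparison is qualitative: the MI estimate depends on the
  discretisation, for which no canonical choice exists.
* The filter's passband sacrifice below 2 Hz is the right trade for FI-type
  features but would be wrong for features that need faithful step-band
  amplitudes; swap in a longer filter via `design_fir()` if so.
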