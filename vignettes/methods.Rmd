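---
title: "Methods: pulse-waveform features and Gaussian-process blood-pressure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse-waveform features and Gaussian-process blood-pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cuff sphygmomanometry cannot track blood pressure continuously through a
smoking session, but the photoplethysmogram (PPG) and the ECG encode
pressure indirectly: vascular tone shapes the pulse morphology, and the
pulse transit time (PTT) from the R-wave to the pulse arrival shortens as
pressure rises. `pulsebp` implements the full estimation chain — signal
conditioning, fiducial detection, feature extraction, dataset expansion,
dimensionality reduction, Gaussian-process regression (GPR), and phase-wise
reporting — together with a synthetic-data module that makes every stage
testable without access to a measurement cohort.

# The synthetic generator

## Beat model

One PPG beat is the sum of two Gaussians over the beat period $T$:

$$y(t) = A_s e^{-(t - c_s T)^2 / 2 w_s^2} + A_d e^{-(t - c_d T)^2 / 2 w_d^2}$$

with the systolic wave at $c_s = 0.22$ of the cycle ($w_s = 0.05$ s,
$A_s = 1$) and the diastolic wave at $c_d = 0.59$ ($w_d = 0.09$ s,
$A_d = 0.45$ by default). The dicrotic notch is the local minimum of the
sum between the two centers — roughly 40–45 % of the cycle for the
defaults, typical of a young-adult finger PPG. Centers are period
fractions (morphology scales with heart rate); widths are in seconds (wave
sharpness does not). Because the waveform is analytic, the generator reads
its ground-truth fiducial indices directly off the rendered noise-free
template, and detector accuracy can be scored in samples.

The ECG channel is a train of narrow Gaussian R-waves (width 12 ms): only
R-peak timing is consumed downstream (heart rate and PTT), so no attempt
is made at P/QRS/T morphology.

## Noise, modulation, and phases

Records add, on top of the beat train: white Gaussian noise (SD 0.005 a.u.,
about 0.5 % of pulse amplitude — a clean finger-probe recording), 50 Hz
mains interference (amplitude 0.02 a.u.), sinusoidal baseline drift
(0.04 Hz), and respiratory-like amplitude modulation (0.1 Hz). Phase
presets modify a subject's baseline per protocol phase: heart-rate shift
(+12 bpm during smoking, decaying through the after-intervals — the
during value mirrors the observed 88 → 100 bpm pulse-rate rise),
amplitude-modulation depth, notch relocation, drift amplitude, and a PTT
shift (−10 ms during), the vasoconstrictive channel that moves pressure.

Two design principles fix the preset magnitudes, for which no quantitative
literature values exist:

* **Subject heterogeneity.** Modulation depth and drift are subject traits
  (Gaussian jitter, SD 0.08 and 0.04), and the acute response is scaled by
  a per-subject gain (SD 0.25): real cohorts contain responders and
  non-responders, and amplitude fluctuation varies strongly between
  subjects and habits.
* **Overlap.** Phase effects on nuisance parameters stay within about one
  subject-SD of the baseline, so the phases overlap in feature space
  rather than separating into disjoint clusters. Without this, a model
  trained on baseline windows sees later-phase windows as entirely
  out-of-support and degenerates to predicting its prior mean, which
  erases the physiological signal the phase analysis is after.

## The generative pressure law

Cohort rows carry ground-truth pressures from a linear law on the window's
true generative parameters:

$$\mathrm{SBP} = a_0 + a_1/\mathrm{PTT} + a_2\,\mathrm{AI} + a_3\,\mathrm{HR} + \varepsilon$$

(default $a_1 = 25$ mmHg·s, $a_2 = 5$ mmHg, $a_3 = 0.15$ mmHg/bpm;
DBP uses 15 / 3 / 0.05) with $\varepsilon \sim N(0, \sigma^2)$,
$\sigma = 2$ mmHg by default. Intercepts are calibrated so the default
subject distributions (HR $83 \pm 13$ bpm, PTT $0.25 \pm 0.03$ s, AI
$\approx 2.3 \pm 0.3$) give SBP $\approx 122 \pm 12$ and DBP
$\approx 75 \pm 8$ mmHg — a young, mostly male cohort. The inverse-PTT
term dominates; the HR term encodes sympathetic coupling, so the acute
heart-rate rise co-occurs with a systolic rise. The law asserts no deeper
physiology: it exists so that downstream regression has a known target to
recover, with exact recovery achievable as noise goes to zero.

Seeding is hierarchical: one root seed, per-subject seeds derived as
`(root·1000003 + index·7919) mod (2^31 − 1)`, so cohorts are reproducible
and individual subjects can be regenerated in isolation.

## What the generator does not emulate

Motion artifacts beyond additive drift, respiration-coupled frequency
modulation, arrhythmia, probe-contact changes, and any validated
hemodynamic model. Passing tests demonstrate that the pipeline recovers
structure *of the kind the generator produces*; they do not certify
accuracy on clinical recordings.

# Conditioning

Band-passes are Butterworth cascades applied forward–backward
(`signal::filtfilt`), so they are zero-phase and fiducial timing is
untouched. The high-pass stage is pinned at order 2: a 0.05 Hz corner at
500 Hz sampling (normalized frequency 2·10⁻⁴) is numerically stiff, and
higher-order transfer-function designs are unreliable there. The low-pass
stage defaults to order 5, which leaves under 1 % of a 50 Hz tone inside
the 0.05–30 Hz PPG band after the bidirectional pass (order 4 leaves
1.65 %). The mains notch is a 2nd-order band-stop over 48–52 Hz. Min-max
normalization to [0, 1] follows filtering and precedes detection; a
constant signal raises an explicit degenerate-input error rather than
returning zeros. The Welch PSD (Hann window, 50 % overlap, 4 s segments)
is provided for quality control.

# Fiducial detection

Systolic peaks are prominence-filtered local maxima (threshold: 25 % of
the signal range) with an *adaptive* refractory distance: 70 % of the
dominant beat period estimated from the autocorrelation maximum over
physiological lags (0.25–2 s). A fixed 0.25 s floor alone fails at low
heart rates, where the diastolic wave sits far enough from the systolic
peaks to survive as a spurious detection; scaling the refractory window
with the actual periodicity suppresses it across the full 40–180 bpm
range. Feet are minima between consecutive peaks.

Two notch rules ship:

* `d1_zero` (default): the first rising zero-crossing of the first
  derivative strictly between the systolic peak and the next foot — by
  construction the local minimum of the pulse, and unbiased on smooth
  waveforms.
* `d1_peak`: the local maximum of the first derivative in the same
  window, i.e. the steepest point of the diastolic rising edge. On smooth
  two-Gaussian pulses this point sits systematically *after* the true
  notch by roughly half the diastolic rise time (10–20 samples at
  500 Hz); on waveforms with a sharp incisura the two rules nearly
  coincide. The biased variant is retained because some detection practice
  identifies the notch this way; the unbiased rule is the default so that
  sample-level accuracy claims are meaningful.

Beats with no qualifying extremum keep an NA notch — an absent notch is
represented, never fabricated — and the notch-dependent features of such
beats are excluded from aggregation. The manual-verification step of
bench practice is replaced by an automated gate: beats whose peak-to-peak
interval or systolic amplitude falls outside median ± 3 MAD are dropped,
each with a logged reason.

# Features

Per beat: systolic amplitude (peak − foot), diastolic amplitude
(post-notch diastolic-wave peak − foot; the measurement landmark is this
package's choice, since "diastolic amplitude" has no universal
definition), systolic/diastolic areas (trapezoidal, above the foot level,
foot→notch and notch→next foot), IPA = SA/DA, systolic and diastolic
times, pulse interval, stiffness index sa/DT, PPI and PR = 60/PPI, FWHM
(with sub-sample interpolation at the half-height crossings),
sa/DT ratio, augmentation index sa/Da, per-beat heart rate 60/T_RR, and
the two transit times PTT_f (R → foot, measured against the same R-peak
paired with the systolic peak; slightly negative values are legitimate at
slow heart rates, where the upstroke begins before the R-wave of the
*next* cycle's pairing) and PTT_p (R → peak).

Aggregation applies four statistics per series — mean, sample SD,
adjusted Fisher–Pearson skewness, and Pearson (non-excess) kurtosis; the
estimator conventions are pinned so the layer is bit-reproducible, and
degenerate (zero-variance) series report 0 with a log note. Window
scalars: zero-crossing rates of the PPG, its first two derivatives, and
the ECG, plus Shannon energy entropy $E = -\sum y^2 \ln y^2$ (with
$0\ln 0 = 0$). Two details:

* The zero-crossing rate defaults to *sign-change* semantics,
  `count(y_n y_{n-1} < 0)/(N−1)`, computed about the signal mean — a
  [0, 1]-normalized trace never changes sign, so the raw count would be
  identically zero. A literal count-negative-samples variant is available
  behind a flag.
* Entropy inputs must lie in [−1, 1]; derivative channels are scaled to
  unit maximum first, and out-of-range inputs warn.

The feature registry is configuration (`inst/extdata/feature_presets.yaml`),
not code. The `core` preset spans exactly 65 features: 4 statistics ×
(14 morphology series + heart rate) + 4 zero-crossing rates + the PPG
entropy. The `full` preset (75) adds the PTT statistics and derivative
entropies; it is the cohort default because the generative law acts
through PTT, which the 65-feature enumeration does not cover — the
morphology literature itself is not consistent about which features made
up its 65, naming PTT statistics among selected features while counting
them out elsewhere.

# Dataset expansion and splitting

Expansion sorts rows by reference DBP (ties by subject id), fits a cubic
spline per numeric column over the row rank, and evaluates all columns on
`target_n` evenly spaced ranks (default 870 from 84). Knot positions
reproduce the measured rows exactly and keep a `measured` provenance
flag; all other rows are `interpolated`. This rank-ordered per-column
construction is the simplest concrete reading of "cubic interpolation
expands the dataset", and it has an important property: any linear
relation between columns (such as the generative law between features and
pressure) is preserved exactly by the interpolation, so expansion does
not destroy recoverability.

It has an equally important pathology: **interpolated rows are not
independent samples**. Splitting after expansion (the default, matching
the modelled analysis) places interpolated neighbours on both sides of
the train/test boundary, so held-out error collapses far below the
observation noise — the mechanism behind sub-0.5 mmHg "test" RMSE on data
carrying 2 mmHg noise. The pipeline therefore also offers
`split_before_expand = TRUE`, which splits the measured rows first and
expands only the training partition; its test error is an honest estimate.
The default remains expand-then-split deliberately, as the behaviour under
study.

The 85/15 split draws a seeded shuffle; the test-set size is
round-half-up of n·0.15, so 870 rows give 739 + 131. Row-level outlier
removal (median ± 3 MAD per feature column) errors out if more than half
the table is flagged, treating that as an upstream failure rather than
data cleaning.

# Reduction

Features are standardized with training statistics (they carry
heterogeneous units), constant columns are dropped with a message, and
PCA follows with a pinned sign convention (largest-magnitude loading
positive), making the decomposition deterministic. The default
selection keeps k = 12 components; a cumulative-explained-variance
threshold mode picks the minimal k reaching the threshold. Because
reduced features are often reported by original-variable names — which
true principal components do not have — a loading-selection mode ranks
original features by their maximal absolute loading across the retained
components and returns the top names; it reproduces naming semantics but
the regression operates on component scores.

# Gaussian-process regression

For target $y$ (SBP or DBP, mmHg) with inputs $X$ (the PC scores), the
model is a zero-mean GP on centred targets with prior mean equal to the
training-target mean and covariance from one of: exponential
$e^{-r/\sigma}$, Matérn 5/2
$(1 + \sqrt5 r/\sigma + 5r^2/3\sigma^2)e^{-\sqrt5 r/\sigma}$, RBF, or
linear. The defaults follow the modelled configuration: Matérn 5/2 for
SBP (preset $\sigma = 0.1367$) and exponential for DBP (preset
$\sigma = 0.0807$), with $\sigma$ interpreted as the kernel
*length-scale* (the term is ambiguous in common usage; the
output-scale reading would not interact with a 0.01–0.5 grid).

Inputs are scaled with training statistics: each column shifted to zero
minimum, and **all columns divided by the single largest training
range**. This maps the dominant input direction onto [0, 1] — so the
0.01–0.5 tuning grid spans short- to long-range correlation — while
preserving the relative variances of the reduced features. Per-column
min-max scaling was rejected: it inflates low-variance noise components
to the same scale as the leading ones, which both drowns the informative
displacement of phase-shifted windows and drags the tuned length-scale to
the grid boundary. Under the common scaling, cross-validated tuning
selects interior length-scales (typically 0.2–0.4) bracketing the preset
values.

`gpr_tune_sigma()` evaluates the grid (default 0.01–0.5, step 0.01) by
seeded fivefold cross-validation and returns the minimiser of mean CV
RMSE, ties toward the smaller length-scale. Grid search is used as the
reference implementation because it is exactly reproducible; the noise
level is not tuned. The observation-noise variance defaults to a 10⁻⁴
jitter — with it, the posterior mean interpolates the training targets,
which is the intended behaviour for the expansion-leakage regime. When
the model is applied across phases (trained on baseline, predicting
later-phase windows), a noise level near the known observation-noise
variance is the appropriate setting: an interpolating GP would otherwise
memorise target noise through the high-variance window statistics and
replay it at shifted inputs. Duplicated inputs with conflicting targets
and zero noise raise an ill-conditioning error that points at
`noise_level`.

Training is restricted to the `"before"` phase whenever a phase column is
present (the protocol trains on baseline and applies the model to later
phases); evaluation reports mean error, residual SD, RMSE, MAE, and R²
(NA on zero-variance references).

# Numerical and procedural choices, collected

* Zero-phase filtering throughout; HP order 2 / LP order 5 Butterworth;
  notch 2nd-order band-stop.
* Peak picking: prominence ≥ 25 % of range, refractory = 0.7 × dominant
  period (autocorrelation), floor 0.25 s.
* Notch rule default `d1_zero`; `d1_peak` available.
* Outlier gates: 3 × scaled MAD, beats and rows; rejection logged;
  row-level flood (> 50 %) is an error.
* Skewness type-2 / kurtosis Pearson non-excess (both 0 for degenerate
  series, with a message).
* Split: test = round-half-up(n(1−frac)); seeded shuffle; manifests
  exportable as JSON.
* PCA sign: largest-|loading| positive; constant columns dropped.
* GP: common-denominator input scaling; prior mean = training mean;
  jitter 10⁻⁴; CV ties toward smaller σ; Cholesky solves.
* Seeds: root → per-subject via the documented linear derivation; every
  stochastic step (generation, splits, folds) takes an explicit seed.

# Problem sizes in the test suite

The suite exercises the study conditions at sizes chosen for a
single-CPU run: 30-s records at 500 Hz for the conversion and cardinality
checks; 100 seeded 10-s noise-free records for fiducial recovery (median
error ≤ 2 samples for peaks/R-peaks, ≤ 3 for notches); 84-subject
single-phase cohorts expanded to 870 rows for law recovery (held-out RMSE
≤ 4 mmHg at 2 mmHg law noise, ≤ 0.5 mmHg at zero noise, length-scales
tuned on the full grid); and an 84-subject two-phase cohort for the
directional check that predicted SBP rises during smoking. Module tests
use smaller synthetic tables built in code.

# Known limitations

* The two-Gaussian beat lacks the asymmetric upstroke and sharp incisura
  of real pulses; detector biases measured here (notably for `d1_peak`)
  will differ on clinical data.
* The generative law is linear and three-parameter; it demonstrates
  recoverability, not physiology. Coefficients are config, not truth.
* Expand-then-split inflates apparent accuracy by construction; honest
  generalisation error requires `split_before_expand = TRUE`.
* The phase presets encode plausible, overlapping effect sizes; only the
  during-phase heart-rate rise has an observed anchor. The post-phase
  decay profile and the notch-relocation magnitude are nominal.
* DBP's documented during-phase *drop* (a compensatory effect) is not
  modelled; the presets move both pressures through the same PTT/HR
  channels, so only the systolic direction is asserted in tests.
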