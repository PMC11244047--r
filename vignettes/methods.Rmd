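---
title: "Methods: synthetic IMU movement recognition and intervention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic IMU movement recognition and intervention analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures implemented in
`bafawubu`, the choices made where the design was genuinely open, and what
the package's synthetic experiments do and do not demonstrate about real
sensor data.

## The recognition problem

An arm-worn six-axis IMU (accelerometer ±16 g, gyroscope ±2000 °/s)
records a practitioner performing the Bafa Wubu routine, which decomposes
into seven motion sets (WOF, LF, RBB, PB, PPS, ELS, SKR). The analysis
chain classifies every 2 s window of the recording into one of the seven
classes, counts movement repetitions from the window-label sequence, and
flags sessions whose counts deviate from the designed seven repetitions
per movement. A second, statistical arm evaluates an 8-week intervention
in which one group of elderly practitioners received weekly feedback from
this recognizer.

## Synthetic data generator

No raw recordings were released with the study this package re-implements,
so a seeded generator stands in for them. Its signal model is the simplest
one that makes every preprocessing step consequential:

* a static 1 g gravity component along a class-specific sensor
  orientation (forward, backward or lateral tilt of the arm);
* per-axis sinusoids at a class-specific fundamental frequency between
  0.2 and 2 Hz — tai chi tempo, safely below the 5 Hz filter cutoff —
  plus a 0.3× second harmonic, on both accelerometer (0.06–0.65 g) and
  gyroscope (4–90 °/s) axes;
* optional high-frequency interference (default 25 Hz, above the cutoff)
  and white measurement noise, added before clipping to the sensor
  ranges so saturation behaves like a real sensor;
* the stationary stance SKR has a strictly smaller gyroscope amplitude
  than every travelling class, mirroring its defining property.

Scripted sessions concatenate movement events with 1 s linear cross-fades
labeled `"transition"`, so that the window-labeling rules for mixed
windows are exercised. The designed full session
(`bafa_wubu_script()`) performs the seven-movement sequence in rounds,
seven repetitions each of 4 s — 49 events and about four minutes,
matching the dedicated data-collection bout of the precision-intervention
protocol. The raw sampling rate is not documented for the deployed
device; the generator defaults to 200 Hz so that both the 5 Hz filter and
the 4:1 downsampling to 50 Hz do real work.

A nearest-centroid oracle on per-window channel means and variances
separates the seven default signatures perfectly on noiseless data; this
guarantees the classes are learnable before any network training is
interpreted. What the generator does *not* emulate: biomechanically
realistic limb kinematics, orientation drift, inter-subject style
variation beyond the seed, or sensor bias. Perfect synthetic accuracy
therefore shows the pipeline is correct and the architecture adequate for
its receptive field — not that real-world accuracy would match.

## Preprocessing

**Filtering.** The filter family and order are not documented, so the
package uses a 4th-order Butterworth applied forward and backward
(`signal::filtfilt`), the standard choice for human-movement signals: the
zero-phase property preserves waveform timing, which windowed labeling
relies on. The stock `filtfilt` leaves large edge transients (a constant
input came back wrong by 0.88 near the edges), so the signal is padded by
odd reflection over roughly eight cutoff periods before filtering;
constants then pass through with error below 1e-6 and DC gain is exactly
1. The two passes square the magnitude response: a 2 Hz tone keeps
amplitude 0.999, a 25 Hz tone is attenuated below 2e-6, both matching the
analytic Butterworth response.

**Downsampling to 50 Hz.** Plain decimation when the source rate is an
integer multiple of 50 Hz. For non-integer ratios the package interpolates
with cubic splines onto the target time grid: under the caller contract
the signal is already low-passed to 5 Hz, a 10× oversampling at the new
Nyquist, where spline interpolation is spectrally accurate and exactly
time-aligned. (The available polyphase resampler was rejected after
measurement: it delayed the signal by about 3.5 samples without
compensation, which would shift every subsequent window boundary.)

**Segmentation and labeling.** Uniform sliding windows, 2 s long with 50%
overlap, giving `floor((n − L)/H) + 1` windows of 100 samples at 50 Hz.
The study states the window geometry but no labeling rule, so windows are
labeled by majority vote over per-sample labels, transition samples
excluded; ties go to the window's center sample, and windows containing
only transition samples are dropped. Channels are z-scored with training
set statistics (stored in the fitted model), because accelerometer and
gyroscope units differ by two orders of magnitude.

## The temporal convolutional network

The recognizer is a stack of identical blocks — dilated 1D convolution
over time, batch normalization, ReLU, dropout, in that order — with **no
residual connections**, followed by global average pooling over time and
a dense softmax layer over the seven classes. The deployed configuration
is 20 blocks with dropout 0.44 and 1000 training epochs; those are the
package defaults.

Choices the source architecture leaves open, and how they were fixed:

* **Kernel, filters, dilations.** Kernel 3, 32 filters. Dilations cycle
  1, 2, 4, 8, 16, 32 across blocks (uncapped doubling over 20 blocks
  would be astronomically dilated), scaled by the smallest integer that
  makes the receptive field `1 + Σ (kernel − 1)·d_i` cover the
  100-sample window; configuration is rejected otherwise. At 20 blocks
  the cycle is used as-is (receptive field 385); a scaled 4-block model
  gets dilations 4, 8, 16, 32 (receptive field 121).
* **Head.** The architecture audit demands a single dense softmax head,
  while the hyperparameter search must be able to vary "neurons in the
  fully connected layer". Default `dense_units = 0` puts pooling straight
  into the softmax layer (single dense head); `dense_units > 0` inserts
  one hidden ReLU layer and is searchable.
* **Optimizer and loss.** Adam (learning rate 1e-3) on categorical
  cross-entropy, minibatch 64 — the standard recipe for softmax
  classification.
* **Split.** Two-thirds training, one-third validation. Whether the
  original split was per window or per practitioner is not stated;
  the default here is subject-wise, which prevents leakage of a
  subject's overlapping windows across the split, with window-wise
  available for comparison.
* **Determinism.** All initialization, shuffling and dropout draw from a
  seeded RNG; equal seeds give bit-identical training histories. The
  backward pass is verified against central finite differences.
* **Hyperparameter search.** Seeded random search over bounds on
  `n_blocks`, `dense_units`, `dropout` and `learning_rate` (log-uniform),
  scored by final validation accuracy; divergent trials (non-finite
  loss) score `-Inf`.

The engine is written in base-R linear algebra: a batch is a
`(B·T) × C` matrix, a dilated convolution is `kernel` shifted matrix
products, and batch normalization runs per output channel with running
statistics for inference.

## Evaluation

Confusion matrices are 7×7 in fixed class order, rows true, columns
predicted. Per-class accuracy follows the published validation table's
semantics — recall, `100·true/(true + false)` within the true-class row —
rounded half-up to one decimal. One caveat found while verifying that
table: no single rounding rule reproduces all seven printed percentages
from the printed counts (three rows match only under truncation, one only
under rounding half-up), so the package treats agreement to one unit in
the last printed digit as exact reproduction. Classes with no true
instances report `NA`, not 0.

## Repetition counting

The deployed system classified windows once per second and incremented a
counter per recognized movement; the event rule itself is not documented.
The package's rule: a sliding mode filter of width 3 first removes
isolated label flickers (applied left to right, so ties resolve to the
already-smoothed previous label — an alternating sequence settles on its
first label); maximal runs of at least `min_run = 2` identical labels
then become events, transitions discarded. The rationale for two windows
minimum: with 50% overlap each second of signal is covered by two
windows, so a single-window detection is unreliable. On noiseless
scripted sessions classified by the ground-truth oracle this recovers
every scripted repetition count exactly; both parameters are configurable
for sensitivity analysis. Whether consecutive repetitions of the *same*
movement should merge into one event is undecidable from the study
design; the designed session interleaves classes in rounds, so the
question does not arise there.

## Intervention statistics

The cohort generator draws each subject's (pre, post) pair from a
bivariate normal with the published group means and SDs (21 precision,
29 standard completers) and correlation `rho`. The pre/post correlation
was not reported; 0.7 is a typical eight-week test–retest correlation
for balance, grip strength and questionnaire outcomes, and it is a
plain generator parameter. Because the raw data are unavailable, the
published p-values are *not* reproduction targets — only distributional
properties of the method are: the interaction test's type-I error
calibration under a null cohort, and its power under a one-within-SD
shift of the precision group's post mean at the study's sample sizes
(consistent with the reported 80% post-hoc power).

The 2 (group) × 2 (time) mixed ANOVA is computed by orthonormal
subject contrasts: the sum contrast `(pre + post)/√2` carries the group
effect against subjects-within-group error, the change contrast
`(post − pre)/√2` carries time and group×time against the
time-by-subjects error. Effects use Type III (drop-one, unweighted
means) sums of squares via effect-coded regression — the convention of
the commercial software used in the original analysis, and the one that
matters for the unbalanced 21 vs 29 groups. Partial eta squared is
`SS_effect/(SS_effect + SS_error)`. The implementation is validated
against a definitional sums-of-squares oracle on balanced toy data and
against an independent Type III repeated-measures implementation on
unbalanced data. Degenerate inputs (no within-subject change anywhere)
return F = 0 rather than 0/0. Shapiro–Wilk normality uses the standard
library implementation and does not gate the ANOVA, since the original
analysis reports both without a branching rule. Follow-up contrasts
include both a post-only Welch test and a change-score Welch test,
because the exact contrast behind a published between-group difference
marker is ambiguous.

## Problem sizes and numerical tolerances

The packaged experiments run at desk scale by design: recognition
experiments use 21 simulated subjects × 2 rounds of the seven-movement
sequence (≈1430 windows), a 4-block/16-filter network and 100 epochs —
enough for the separable synthetic task to reach its ceiling — rather
than the original 70 practitioners and 1000 epochs. Null calibration
uses 2000 replicates (binomial SE ≈ 0.005 at α = 0.05) and power 500
replicates. Probability vectors are checked to 1e-6, gradients to 1e-4
relative, ANOVA oracles to 1e-9, and zero-variance channels are floored
at sd = 1e-8 with a warning.

## Known limitations

* Synthetic signatures are stationary and subject-invariant; real
  recognition accuracy (82–94% per class in the original validation)
  cannot be reproduced or predicted from them.
* The exact convolution hyperparameters, optimizer and split unit of the
  deployed network are unknown; published accuracies do not identify a
  unique architecture.
* The counter replays recordings offline; true streaming latency,
  transport and UI concerns are out of scope.
* SF-12 and BDI enter as scalar scores only; item-level scoring,
  dropout modeling and power-analysis software replication are out of
  scope.
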