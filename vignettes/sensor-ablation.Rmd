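---
title: "Methods: synthetic gait studies and sensor-ablation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait studies and sensor-ablation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gaitablate)
```

`gaitablate` implements a complete sensor-ablation study for wearable-sensor
activity recognition: synthetic multimodal gait sessions, windowed feature
extraction, principal-component similarity diagnostics, Gaussian-SVM
classification under leave-one-trial-out cross-validation, and pairwise
effect-size comparison of sensor subsets. This vignette is the package's
account of the underlying methods: the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic studies do and
do not demonstrate.

## The study design being emulated

A session is one treadmill trial: commands of *stand*, *walk*, *run* and
*sprint* are issued every 10 s for 150 s, in an order that changes between
trials so activity-to-activity transitions are spread roughly evenly. The
treadmill is self-paced, so each subject realises the commands at their own
preferred speeds; ground truth is therefore defined by per-subject speed
thresholds rather than by the commanded schedule. Each subject contributes
six trials, and five default subject profiles span walking thresholds of
1.2–1.6 m/s and running thresholds of 2.4–3.3 m/s. Instrumentation is eight
combined sEMG/accelerometer units (gastrocnemius, tibialis anterior,
hamstring, vastus medialis, both legs), two force plates, and the belt-speed
log — 19 channels.

## The synthetic-session generator

Raw recordings of this kind are typically unavailable for redistribution, so
the generator is first-class, tested code rather than a fixture. Its purpose
is narrow and explicit: to produce sessions with the *feature-level
statistical structure the analysis exploits*, not to simulate physiology.

**Belt speed.** The commanded activity defines a target speed (the profile's
preferred speed for that activity); the realised speed follows it with a
first-order lag (`response_lag`, default 1.5 s — the subject reads the
command, then acts), plus zero-mean Gaussian noise (SD 0.05 m/s), clamped at
zero. Preferred speeds default to the midpoints of each subject's labelling
bands; the sprint band has no upper edge, so the sprint preferred speed is
set to 1.15 × the running threshold, a modest self-paced sprint.

**Stride phase.** A shared kinematic backbone for all gait-dependent
channels: stride frequency is `stride_frequency_base + 0.18 Hz·s/m × speed`
(defaults give ≈ 1.1 Hz at typical walking, ≈ 1.4 Hz at fast running), and
its integral defines the stride phase, frozen while standing.

**sEMG.** A surrogate: band-limited (20–450 Hz) unit-RMS Gaussian carrier,
multiplied by a stride-cycle envelope (depth 0.5 when moving, left and right
sides in anti-phase) and an activity-dependent RMS gain. Two deliberate
structures are planted. First, the walk-to-run RMS contrast is larger for
shank muscles (0.08 → 0.22 mV) than thigh muscles (0.10 → 0.13 mV): distal
muscles change their activation profile more between gaits, and this is the
contrast that lets lower-leg sensor sets outperform upper-leg sets
downstream. Second, the carrier is a mixture of a low (20–150 Hz) and a high
(150–450 Hz) band whose mixing weight rises with activity intensity, so the
median frequency feature shifts with activity.

**Accelerometers.** Constant 1 g gravity plus stride-frequency harmonics
whose amplitude grows linearly with speed, with a larger gain for
shank-mounted (0.28 g·s/m) than thigh-mounted (0.10 g·s/m) units — distal
points on a swinging leg see larger accelerations. Harmonic phases are fixed
rather than randomised so that left and right units stay exactly anti-phase,
and the dominant vertical harmonic peaks mid-stance; this keeps the windowed
magnitudes of all side-specific channels coherent with the loading of the
ipsilateral plate, which is what allows a left/right-asymmetry component to
form in the PCA.

**Force plates.** Standing splits body weight evenly with slow mediolateral
sway. Gait uses per-leg stance profiles on the stride phase: walking has a
double-peaked shape with a stance duty factor of 0.60, so the two plates
overlap (double support); running and sprinting use single-peaked shapes
with duty factors 0.35 and 0.30, so both plates are simultaneously zero
during flight. Peak forces are scaled so the cycle-mean total force equals
body weight (running peaks ≈ 2.2 × body weight > walking peaks), forces are
never negative, and stance noise is applied only where a plate is loaded so
flight samples stay exactly zero. A configurable fraction of strides can
have their left/right plate assignment swapped to emulate cross-plate
strikes; the default is 0.

**Determinism.** One study seed fans out through a counter-based hash to
per-schedule and per-channel sub-seeds (all below 2³¹), so a session is
bitwise reproducible as a whole and channel by channel.

**Sampling rates** are not dictated by the emulated study design and are
declared defaults: sEMG 1000 Hz, accelerometers 100 Hz, force plates
1000 Hz, belt speed 300 Hz. The speed rate is chosen above twice the 50 Hz
labelling filter cutoff so that filter is realisable; all rates are
configurable in `session_config()`.

## Ground-truth labelling

The emulated protocol describes filtering the *class labels* with a 6th-order,
50 Hz Butterworth filter; categorical labels cannot be filtered, and the
stated purpose is smoothing speed noise, so the implementation filters the
speed trace and then thresholds it. Filtering is zero-phase
(forward–backward) so labels are not lagged, with odd-reflection padding to
absorb the filter transients at the trace ends. Since a noisy, filtered
speed never equals exactly zero, "speed = 0 → stand" is implemented as
|v| < 0.05 m/s. Threshold bands are upper-inclusive: walk is
(0, walk_upper], run (walk_upper, run_upper], sprint above. A window takes
the majority label of the samples it contains, with an exact tie broken
toward the label of the sample nearest the window centre (the aggregation
rule is not dictated by the design; majority is the natural choice and the
tie rule makes it deterministic).

## Feature extraction

Windows are 0.5 s with 0.30 s overlap (step 0.2 s), half-open on the right,
trailing partial windows dropped — a 150 s trial yields 748 windows. Streams
keep their native rates; each feature uses whatever samples of its source
channel fall inside the window. Choices on points the design leaves open:

- *ACC* is the **mean of per-sample norms** (robust to within-window
  oscillation), not the norm of the mean.
- *H1–H3* are **fractions**, not counts, so they are invariant to sampling
  rate; deviations are two-sided (|x − x̄|/s), and a zero-variance window is
  (1, 0, 0) by convention. The three fractions always sum to 1.
- *MF* uses a single Hann-tapered periodogram per window (windows are too
  short for Welch averaging to pay off), with linear interpolation between
  spectral bins of the cumulative power; an all-zero window maps to 0 Hz.
- *FPSD* uses the n − 1 sample SD, 0 for a single-sample window.

z-scoring is fit **per training fold** and applied frozen to held-out
trials. The emulated protocol states normalization but not the fold
discipline; fitting on all data would leak test statistics into the scaler
and bias cross-validation. Per-trial normalization (used for the per-trial
PCA diagnostics) is available by simply fitting a normalizer on a trial.

## PCA similarity

Per-trial PCA models (each trial z-scored on its own windows) are compared
through the angles between loading vectors. The PCA sign ambiguity is fixed
by making each loading column's largest-magnitude entry positive; angles are
computed *before* folding, so the sign convention cannot hide genuine
dissimilarity. Supplementary-angle folding (θ → 180° − θ for θ > 90°) is
applied only to like-component comparisons, reported in [0°, 90°]; non-like
angles stay unfolded in [0°, 180°]. The study-level matrix pools every
unordered trial/subject pair with equal weight (the emulated analysis does
not state a weighting) and uses the standard midpoint-average median for
even counts. Reference correlations (PC1 vs windowed mean belt speed, PC2 vs
windowed mean left-minus-right plate force) are absolute Pearson
correlations — the estimator is a declared choice, Spearman is available via
an argument — summarised by median and IQR across trials.

## Classification

Per subject and per fold (one trial held out): fit normalizer → PCA on the
normalized training windows → keep the first `min(3, n_features)` scores
(so two-feature ablation cases remain runnable) → train a multiclass
one-vs-one Gaussian-kernel SVM → project the held-out trial with the
training centre and loadings and score it. SVM hyperparameters are not
dictated by the emulated protocol; defaults are box constraint 1 and a
kernel scale from the median pairwise distance of the training scores, both
exposed as arguments. Accuracy is reported raw (four classes) and with
run/sprint confusion merged — running and sprinting differ mainly in speed,
not gait mechanics. Fold summaries use the median and the unscaled MAD over
all subject × fold accuracies. Class imbalance (sprint windows are fewest)
is reported through per-class support, sensitivity and specificity; no
resampling is applied.

## Ablation and effect sizes

Cases 1–6 retain whole wearable units (sEMG + accelerometer features of the
selected muscles), with force plates included in Cases 1, 4 and 5; Cases 7
and 8 are accelerometer-only. The emulated design describes Case 7 as one
accelerometer per leg segment and Case 8 as one per shank; an alternative
reading of the accompanying text ("four accelerometers") conflicts with the
figure caption, and the caption's reading (Case 7 = 4 units, Case 8 = 2) is
implemented — it is also consistent with "removing two accelerometers"
between the two cases. Which muscle site hosts those accelerometers is
unstated; the defaults are vastus medialis (thigh) and tibialis anterior
(shank). Feature counts obey
`4 × n_sEMG + n_accel + 2 × n_plates`: 44, 20, 20, 24, 24, 10, 4, 2 for the
eight cases. Cohen's *d* with the pooled SD compares fold-wise accuracies
between cases, for both scoring regimes, labelled by the conventional
thresholds (0.2 / 0.5 / 0.8).

## Problem sizes, tolerances, degenerate inputs

The test suite runs short (20 s) schedules for unit-level checks and
full-length default studies (5 subjects × 6 × 150 s trials) for the
study-level checks; the replicate-study comparison of lower- versus
upper-leg sensor sets uses ten independently seeded full studies. These
sizes were chosen as the smallest that exercise the complete design.
Numerical conventions: window starts are step multiples compared against
sample grids with a 10⁻⁹ tolerance; orthonormality and reconstruction are
checked to 10⁻⁹; H-bin closure to 10⁻¹²; dot products are clamped to
[−1, 1] before `acos`. Degenerate inputs are defined, not errors, where a
convention is defensible (zero-SD histogram window, all-zero MF window,
single-sample SD) and errors where silence would corrupt results
(zero-variance feature at normalizer fit, constant input to a correlation,
empty windows, class missing from a training fold — that fold is skipped
with a warning).

## What passing tests show — and what they do not

The synthetic studies demonstrate that the *pipeline* recovers structure
that is planted in the generator: PC1 tracks speed, like-components align
across trials, lower-leg sensor sets outperform upper-leg sets, merging
run/sprint never hurts. They cannot certify performance on real recordings:
the sEMG surrogate has no motor-unit physiology, accelerometer harmonics are
idealised, and subjects have no biomechanical idiosyncrasies. Accordingly,
synthetic accuracies (≈ 97% median with all sensors) run higher than is
realistic for human data, and the left/right-asymmetry component is coupled
to the plate difference more weakly (median |ρ| ≈ 0.3–0.5) than real gait
exhibits. Two further known limitations: the surrogate's thigh
accelerometers carry little information beyond the shank pair, so Case 7
does not reliably beat Case 8 the way richer real signals would; and
cross-plate-strike corruption is modelled as a clean stride-level swap,
without the partial-contact forces a real mis-strike produces.
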