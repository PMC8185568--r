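---
title: "Detecting freezing of gait from a single wrist-worn IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from a single wrist-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogwatch)
```

## The problem

Freezing of gait (FoG) is a sudden, transient inability to initiate or
continue walking that affects many people with Parkinson's disease. Episodes
range from a fraction of a second to well over a minute, and they matter
clinically because they precipitate falls. A detector that runs on a single
wrist-worn inertial sensor (a smartwatch) is far less obtrusive than the
multi-sensor montages used in laboratory studies, which makes continuous
monitoring — and cue-based intervention — realistic for everyday life.

`fogwatch` implements a complete window-classification pipeline for this
problem: six-channel wrist IMU recordings (tri-axial accelerometer and
gyroscope at 128 Hz) are normalized, cut into overlapping 3-second windows,
labeled `FOG`, `STOP`, or `WALK` from clinician-style interval annotations,
and classified by a compact one-dimensional convolutional network, with
decision-tree and gradient-boosting baselines on classical wrist features
for comparison. Because the clinical cohort this design targets is not
redistributable, the package ships a calibrated synthetic cohort generator
so every stage is testable end to end.

## Windowing and labeling

Windows are `window_s` = 3 s long and advance by `step_s` = 0.25 s
(384 and 32 samples at 128 Hz), so a deployed model emits one decision
every 0.25 s — near-real-time for triggering a cue. The number of windows
in an N-sample recording is `K = floor((N - 384) / 32) + 1`.

Each channel is divided by its maximum absolute value across the whole
training cohort and rounded half-to-even to four decimals; all values land
in [-1, 1] and the rounding makes storage and cross-platform behavior
reproducible. The time column of a recording file, when present, is never
used for indexing: the sample index at a fixed rate is authoritative.

A window is labeled `FOG` when either

1. a FoG episode lies entirely inside the window, however short — this is
   what lets the pipeline see sub-second freezes; or
2. the total FoG time inside the window reaches half the window length
   (1.5 s at defaults).

Otherwise the window takes the majority non-FoG class, ties going to
`WALK`. All intervals are half-open `[start, end)`, which makes overlap
arithmetic exact at block boundaries.

Rule 2 admits two readings for episodes that only partially overlap a
window: threshold the episode's *in-window* time, or the episode's *own
duration*. We adopt the in-window reading as the default: the alternative
would label a window that barely touches a long episode as `FOG` even when
almost everything inside the window is ordinary walking, which is at odds
with the window being the unit of decision. Both readings are implemented
(`fog_rule = "overlap"` / `"episode"`) so the choice is inspectable.

Sessions mixing `STOP` and `WALK` without FoG keep their boundary windows,
labeled by majority; dropping them would bias the class balance seen by the
classifier relative to deployment.

## The window classifier

The default network mirrors the published single-wrist detector:

| stage | operation | output length |
|---|---|---|
| input | 384 samples x 6 channels | 384 |
| conv 1 | 100 filters, kernel 10, valid, ReLU | 375 |
| pool 1 | max, size 3 | 125 |
| conv 2 | 40 filters, kernel 10, valid, ReLU | 116 |
| pool 2 | average, size 2 | 58 |
| head | flatten (2320) -> dropout 0.5 -> dense 3, softmax | 3 |

The three output nodes are the classes `FOG`, `STOP`, `WALK`, in that fixed
order everywhere (serialization, confusion matrices, probability columns).

Several architectural details are not pinned down by the description the
design follows, so they are package decisions: activations are ReLU
(standard for this family), convolutions use valid padding and stride 1,
and pooling is non-overlapping with stride equal to its size. The phrase
"one weight remains per feature detector" is not reachable with the stated
shapes (58 values per filter remain after the second pooling); we therefore
flatten the 58 x 40 map by default and provide a global-average-pooling
variant (`global_pool = TRUE`), which does reduce each feature detector to
one value, behind a flag.

Training minimizes categorical cross-entropy with Adam. Learning rate
(1e-3), batch size (64), maximum epochs (200), early-stopping patience (5)
and the 10% validation split are unstated in the source design and are set
to the community defaults above; all are configurable in
`train_control()`. Early stopping monitors the validation loss and restores
the weights of the best epoch, so a returned model is never worse than any
epoch it saw. The whole run — weight initialization, validation split,
batch order, dropout masks — is a pure function of `seed`. Dropout is
inactive at inference; repeated predictions are identical. No class
weighting is applied by default (the source design is silent); inverse
frequency weights are available via `class_weights = "balanced"`.

The engine is written directly on BLAS matrix products (im2col lowering of
the 1D convolutions, explicit backward passes, Adam in a few vectors) and
is gradient-checked against numerical differentiation in the test suite.

`fog_cnn_search()` samples the stated hyperparameter space — depth 2–5,
kernel size 3–12, 10–100 filters per stage — and selects by inner
validation loss only; test folds are never consulted, by construction.

## Classical baselines

The baselines operate on a canonical single-wrist FoG feature set: per
channel, the statistical moments (mean, SD, variance, min, max, RMS,
energy) plus spectral descriptors from a rectangular-window periodogram of
the mean-removed signal — normalized spectral entropy, dominant frequency,
locomotor-band power (0.5–3 Hz), freeze-band power (3–8 Hz) and their ratio
the *freeze index* — and the spectral descriptors again on the
accelerometer- and gyroscope-magnitude signals (82 features). The exact
composition of the historical feature vector is not published as a list;
this set covers its documented ingredients and is an approximation chosen
once. Band edges follow the standard FoG literature and are configurable.

A zero-variance channel gets spectral entropy 0 and freeze index 0 by
convention rather than NaN. The simple periodogram (no taper, no
averaging) is deliberate: at 384 samples it is the most reproducible
estimator, and the classifiers consume relative band masses, not smoothed
spectra.

Two baselines wrap this feature table behind the same predict interface as
the CNN: a CART decision tree (`rpart`) and gradient boosting (`xgboost`,
multi-class softprob, depth 6, eta 0.3, 50 rounds, single-threaded for
reproducibility).

## Evaluation

`loso_cv()` implements leave-one-subject-out cross-validation: each fold
tests on all windows of one held-out subject, which is the honest estimate
of generalization to a new patient. `kfold_cv()` implements the shuffled
10-fold scheme at *window* level, as in the source design; note that
overlapping windows from one subject then straddle the train/test boundary,
so 10-fold scores are optimistic relative to LOSO — a subject-stratified
variant is available behind `stratify_subjects = TRUE` for honest
comparisons.

Metrics treat `FOG` as positive one-vs-rest: sensitivity TP/(TP+FN),
specificity TN/(TN+FP), F1, and macro-F1. Zero-denominator metrics are
reported as `NA`, never coerced to 0 — with small per-subject test sets
such cases are real. Aggregates are computed both by pooling the fold
confusion matrices and by averaging per-fold metrics; the two answer
different questions and both are in the report, along with per-window
predictions and the fold assignment for full recomputability.

## The synthetic cohort generator

The generator emulates the *shape* of a clinical FoG cohort — eleven
subjects, 10-minute sessions of walking-with-turns interleaved with stops,
FoG episodes embedded in the walking — without claiming biomechanical
realism. The wrist signal is a stylized arm-swing model: per-subject gait
frequency ~ Normal(1.0, 0.1^2) Hz, an arm-swing fundamental with second
harmonic on the accelerometer (plus a 1 g gravity offset on the vertical
axis), swing-coupled gyroscope channels, and periodic yaw-rate pulses for
turns. Stops are gravity plus a low noise floor. FoG episodes attenuate
the locomotor components (factor 0.25) and add a trembling tone with
per-episode center frequency ~ Uniform(4, 7) Hz plus band-limited 3–8 Hz
noise — the classical freeze-band signature that makes the freeze index
discriminative.

Episode durations follow a lognormal law with meanlog 1.0699 and sdlog
1.4302, truncated by rejection to [0.11, 98.8] s. The two parameters are
obtained by quantile inversion so that 50.8% of draws fall below 3 s and
64.7% below 5 s, matching the published percentiles of the emulated
cohort; the truncation range is the published min–max. A two-parameter law
matched to two quantiles cannot also match the published mean (9.12 s) and
SD (15.35 s) exactly — the implied untruncated mean is about 8.1 s — which
we document as a limitation rather than adding parameters; the moments are
therefore not calibration targets. Episodes are placed by a Poisson
process (rate 4.1 per walking minute) thinned to keep episodes disjoint
with at least 2 s of walking between them; the default configuration
realizes roughly 184 episodes per 11-subject cohort in expectation,
matching the emulated cohort's count.

The class-separation dial `gamma` in (0, 1] scales the FoG-distinguishing
components only: at `gamma = 1` FoG windows are spectrally separable; at
`gamma = 0` FoG segments are statistically indistinguishable from walking
while annotations are unchanged. The null condition is what makes the
pipeline falsifiable: a detector evaluated at `gamma = 0` must collapse to
chance, and the test suite asserts that it does.

What passing tests on this cohort show — and what they do not: they show
the pipeline is correct and learnable end to end (windowing, labeling,
training, evaluation all composing properly), and that the expected
ordering between the CNN and the feature baselines emerges. They do not
show clinical performance: real wrist FoG signatures are heterogeneous
across patients, medication states and episode types in ways a stylized
tone model cannot capture, so published clinical scores are not
reproduction targets for this package.

## Problem sizes and numerical choices

The test suite exercises the full LOSO pipeline on a reduced cohort of 4
subjects with 120 s sessions (about 1,900 windows) with the training
budget capped at 12 epochs, and the null control on 3 subjects at 90 s;
these sizes were chosen so the whole suite runs comfortably on a single
CPU while keeping every class represented in every fold's training set.
The full 11-subject, 600 s default (about 26,000 windows) runs the same
code paths and is intended for longer experiments via the command line.

Numerical conventions collected in one place: rounding is half-to-even
(R's `round`); intervals and windows are half-open; label ties break to
`WALK`; class order is always FOG, STOP, WALK; argmax ties in prediction
break by that order; undefined metrics are `NA`; all RNG flows through a
single seed per operation; JSON checkpoints store weights at full
precision so a reloaded model reproduces predictions bit-for-bit.

## Known limitations

* The wrist-signal model is stylized; it supports correctness and ordering
  claims, not clinical accuracy claims.
* The feature baseline approximates a historical feature set whose exact
  composition is unpublished.
* Window-level 10-fold CV leaks overlapping windows across folds by
  design fidelity; use the subject-stratified variant for honest numbers.
* The CNN engine favors clarity and reproducibility over speed; it is
  single-threaded R on BLAS and sized for desk-scale cohorts.
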