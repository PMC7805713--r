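---
title: "Measuring social engagement from keypoint streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social engagement from keypoint streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Social engagement — the degree to which a child is occupied with a person or
task — is usually rated by trained observers. `lmaengage` implements a
quantitative alternative developed for naturalistic child-robot interaction
studies with typically developing (TD) children and children with autism
spectrum disorder (ASD): video recordings are processed upstream into 2D
keypoint streams (25 body and 70 face points per frame, each with a
confidence), trained annotators mark intervals of six *target behaviors*
(eye-gaze focus, vocalizations, smiling, self-initiated interactions,
triadic interactions, imitation), and the package turns both into a
supervised learning problem: predict, from a short window of movement and
facial features, the child's current engagement level.

## The engagement index

Each of the six behaviors contributes a factor of 1/6 while it is active, so
the engagement level at any instant is `(number of active behaviors) / 6`,
taking exactly the seven values 0, 1/6, ..., 1. The integer count 0–6 is the
class label. Design choices here:

* intervals are treated as closed-open `[start, stop)` so abutting events
  tile without double counting;
* overlapping events of the *same* behavior are merged before counting, so a
  behavior can never contribute more than 1/6;
* event timestamps are mapped to frames by rounding `time × fps` to the
  nearest frame index, and engagement is sampled at the full frame rate;
* a single reconciled annotation track is consumed — multi-rater
  reconciliation happens upstream of this package.

An exhaustive enumeration over all \(2^6\) behavior subsets (in the test
suite) confirms the seven levels and their binomial subset counts
(1, 6, 15, 20, 15, 6, 1).

## Laban effort features

Movement dynamics are summarized by the three *effort* features of Laban
Movement Analysis, computed from upper-body keypoints (the recording setup
rarely shows the lower body):

* **Space** — the planar extent of the arm configuration: with \(\vec a\)
  from left shoulder to left hand, \(\vec b\) right-to-left shoulder,
  \(\vec c\) right hand to right shoulder, \(\vec d\) left to right hand,
  \[\mathrm{space} = \tfrac12 |\vec a||\vec d|\sin\theta_1 +
    \tfrac12 |\vec c||\vec b|\sin\theta_2 ,\]
  the summed area of the two triangles spanned by shoulders and hands
  (pixels²). For convex configurations this equals the shoelace area of the
  shoulder/hand quadrilateral, which the tests verify to \(10^{-9}\)
  relative error.
* **Weight** — movement power: \(\sum_i L_i^2 \omega_i^2 \sin\theta_i \cdot
  m_i\) over joints \(i\), a torque-like magnitude.
* **Time** — movement urgency: \(\sum_i |\dot\omega_i|\).

Concrete conventions, where the classical formulations leave room:

* "hands" are the wrists (BODY_25 points 4 and 7) — finger tracking is not
  reliable in this setting;
* the joint set is both shoulders and both elbows, the upper-body joints
  whose angles are well defined from the available points. The shoulder
  angle is measured between the torso axis (neck → mid-hip) and the upper
  arm; the elbow angle between upper arm and forearm. \(L_i\) is the driven
  segment length (upper arm for shoulders, forearm for elbows), in pixels;
* all masses \(m_i\) are 1 — no anthropometric masses are defined for a
  keypoint skeleton;
* in weight, \(\theta\) is the joint's own angle \(\theta_i\);
* **time sums angular accelerations**, not velocities. The classical tables
  are ambiguous (the dotted symbol is glossed "angular velocity"), but a
  constant-speed movement carries no urgency, so the acceleration magnitude
  is the default; `laban_series(..., time_mode = "velocity")` exposes the
  alternative reading;
* derivatives are central differences scaled by fps (one-sided at segment
  endpoints) on phase-unwrapped angles. On noiseless synthetic angle tracks
  they match closed forms to \(O(\Delta t^2)\), which the tests assert;
* coordinates stay in raw pixels — the measurement protocol fixes camera
  placement per session and a per-subject model absorbs scale;
  `normalize_track()` offers inter-shoulder-distance normalization for
  cross-subject experiments, off by default.

Each effort series is aggregated with a **trailing moving mean of 30 frames**
(1 s at 30 fps), stride 1 — long enough to capture a movement pattern,
short enough to follow rapid responses. The first 29 frames of each segment
carry the mean of the frames available so far; windows never span a
gap-split segment boundary.

## The 71-dimensional feature matrix

Facial expression enters as the raw x, y coordinates of the 34 lip and eye
keypoints of the 70-point face model: the 12 eye-contour points, the 20
outer+inner lip points and the 2 pupils — the unique lips+eyes+pupils subset
of size 34. 34 × 2 coordinates + 3 effort features = **71 features** per
frame; the pipeline fails fast on any other width. Rows are aligned by
original frame index (see *Dropped frames* below) and rows with missing
values on either side are dropped and counted.

Classifier inputs are stride-1 sliding **windows of 5 frames** × 71
channels. Each window is labelled with the engagement class of its *final*
frame — a causal convention that supports streaming prediction. An
alternative reading of the network description ("5 channels") as 5 feature
channels would contradict the 71-feature count, so sequence-length-5 is the
default and `seq_len` remains a knob.

## Keypoint stream handling

* **Subject tracking.** Upstream person-ID assignment is unreliable in
  free-moving recordings, so the subject is tracked by positional
  continuity: the first frame seeds with the highest-confidence candidate,
  each later frame takes the candidate whose mean keypoint position is
  nearest the previous selection. Frames with no candidate become absent
  markers.
* **Dropped frames.** The upstream pose estimator can drop frames, so
  absent runs of up to `max_gap_frames = 15` frames (0.5 s) are linearly
  interpolated per coordinate and flagged (`gap_mask`); interpolated
  confidences are set to 0, but the points carry real coordinates and are
  treated as present downstream (absent detections are specifically
  `conf = 0` *and* `x = y = 0`). Longer runs split the track into segments
  — 30-frame features computed across a second of fabricated data would be
  meaningless. Individual keypoints that fail detection inside otherwise
  good frames are interpolated the same way. Alignment with annotations is
  by original frame index throughout, which is also how dropped frames are
  reconciled with annotation timestamps.

## Classifiers

`fit_engagement_model()` fits one of five interchangeable classifiers:

* **cnn** — the package's own 1D convolutional network, written directly on
  BLAS matrix products: Conv1D(64, kernel 3) → Conv1D(128, kernel 3) →
  dropout 0.2 → flatten → dense 256 → dense 256 → dense 7 class scores
  (139,015 parameters at the default input shape), trained with Adam
  (learning rate 1e-3) on softmax cross-entropy. Defaults the network
  description leaves open: 100 epochs, batch 64, early stopping on
  validation loss with patience 10. Class imbalance — low engagement levels
  dominate most recordings — is countered with inverse-frequency class
  weights in the loss. The engagement levels are mutually exclusive, so the
  head is trained as 7-class softmax. Two numerical choices are part of the
  model rather than the pipeline: feature channels are standardized inside
  the network with training-set statistics (raw keypoint features span
  pixels to pixels²·rad²/s², which conditions gradient descent poorly
  otherwise), and prediction runs with dropout disabled, making it
  deterministic. All randomness (initialization, shuffling, dropout)
  derives from the seed, so a fixed seed reproduces the full train→predict
  path bit for bit.
* **svc / rf / dt / knn** — RBF support vector classification (cost 1),
  random forest (100 trees), a decision tree grown without complexity
  penalty, and k-nearest neighbours (k = 5), all on windows flattened to
  5 × 71 = 355-length vectors. These are standard references with standard
  defaults, fitted through `e1071`, `randomForest`, `rpart` and `class`.

## Evaluation protocol

All reported metrics are **class-support-weighted**: per-class precision,
recall and F1 are averaged with weights proportional to true-class support.
The support-weighted mean of recall equals plain accuracy — the package
computes it that way and the tests verify the identity against an
independent confusion-matrix reference.

The protocol description ("10-fold cross-validation, train/test split of
0.8/0.2") is internally inconsistent — 10-fold implies 90/10 — so the
package implements **10 repeated random 80/20 splits**, matching the printed
fractions, with 10% of each training split held out for validation; both the
repetition count and the fractions are knobs. Partitions are audited to be
disjoint and exhaustive on every repetition. Adjacent stride-1 windows
overlap in 4 of 5 frames, so random splitting leaks temporal context between
train and test; this matches the protocol the reference tables were produced
with and is the default, but `split_windows(..., blocked = TRUE)` provides
the leakage-free contiguous-block alternative and is recommended for new
studies.

Personalized models (`evaluate_subject()`) are trained per subject; group
models (`evaluate_group()`) pool all windows of a group (TD, ASD, or
combined) before splitting. `summary_table()` appends unweighted group-mean
rows rounded to 4 decimals (per-subject convention) or 2 decimals
(classifier-comparison convention); the test suite checks that these
aggregations reproduce the published tables of the original 18-child cohort
cell-exactly, which is the only sense in which published numbers are
"reproduced" — the original recordings are available on request only, so
per-subject accuracies cannot be recomputed here.

## The synthetic cohort generator

`generate_cohort()` stands in for the original recordings. Defaults are
fixed study conditions, not tuning knobs:

* 18 subjects (13 TD / 5 ASD), 12,000 frames at 30 fps each (about the
  middle of the original per-subject datapoint range);
* behavior events drawn per behavior from an alternating renewal process
  with exponential on/off durations (means 20 s / 30 s), started in its
  stationary state, giving a stationary activity of 0.4 per behavior and a
  realistic, strongly imbalanced level distribution;
* the active-behavior count at each instant selects the kinematic regime:
  arm-swing amplitude `0.02 × 2^k` rad for class `k` (geometric spacing so
  regimes are separable by construction), base shoulder abduction
  `0.25 + 0.12 k` rad (engaged children open up toward the robot), plus an
  engaged head pose: facial keypoints shift upward by `2 k` px. Smiling
  events widen the lip-keypoint spread by 40%, so facial channels carry
  behavior-specific signal;
* keypoints are produced by 2D forward kinematics from sinusoidal joint
  angles (0.6 Hz), with 1 px Gaussian coordinate noise and frames dropped
  independently with probability 0.01.

`collapse_regimes()` removes every class dependence while keeping the event
process — the resulting labels carry no information about the keypoints,
and classifiers must fall back to the trivial rate. The generator emulates
regime-dependent kinematics and facial configuration; it does **not**
emulate photorealistic motion, camera repositioning, occlusions,
multi-person clutter, or annotation noise. Passing recovery tests therefore
demonstrates that the pipeline's plumbing, features and training are sound —
not that real recordings will reach the same accuracy.

## Problem sizes used in the checks

The end-to-end recovery check runs a 3-subject cohort of 10,000 frames each
(~30,000 windows), with the network's epoch budget set to 25 under early
stopping — it converges well before that on separable data. With the default
separable regimes the network and the random forest both exceed 0.85 test
accuracy (typically ≈ 0.97–0.99); with collapsed regimes the forest settles
at the majority-class rate and the class-weighted network at or below it —
the no-signal optimum of an inverse-frequency-weighted loss is a uniform
posterior, so its null accuracy sits near 1/7 rather than at the majority
rate. Oracle checks (shoelace areas, closed-form derivatives,
confusion-matrix metrics) run at 1,000 random cases each.

## Known limitations

* 2D kinematics only; out-of-plane movement aliases into the effort
  features.
* Only the Effort category of Laban Movement Analysis is implemented (no
  Shape/Body/Space categories), and only space/weight/time within it.
* The engagement index weights all six behaviors equally; no behavior
  detection is attempted — annotations are an input.
* Random-split evaluation inflates absolute accuracies through
  adjacent-window leakage (see above); use blocked splits for honest
  generalization estimates.
* Pixel-scale features make cross-subject models sensitive to camera
  geometry unless `normalize_track()` is applied.
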