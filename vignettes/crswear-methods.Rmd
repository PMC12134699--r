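---
title: "Confounding-resilient smoking gesture detection: models and methods"
author: "crswear maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounding-resilient smoking gesture detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wrist-worn IMUs (3-axis accelerometer + 3-axis gyroscope) can detect
cigarette smoking from its characteristic hand-to-mouth motion, enabling
just-in-time cessation support. The hard part is not recognizing smoking in
isolation but *not* firing on the many everyday gestures that share the same
kinematics — eating, drinking, yawning, applying chapstick, scratching the
face. A classifier trained only on smoking vs. idle data produces false
positives on these confounders; training with the confounders as explicit
negatives (the confounding-resilient approach) is what this package
implements and evaluates, end to end, on a synthetic analogue of a
16-gesture collection protocol.

## Pipeline overview

1. **Synthesis** (`synthesizeDataset`): labeled 6-channel IMU trials
   emulating a collection protocol of 16 scripted activities (15 confounders
   + smoking) in up to 3 postures, 5 s per trial at 20 Hz.
2. **Gravity separation** (`processStream`): a first-order recursive
   low-pass filter per axis, `g' = alpha*g + (1-alpha)*a`, with linear
   acceleration `a - g'`; gyroscope channels pass through unfiltered.
3. **Windowing** (`makeWindows`): the classifier consumes 200 x 6 blocks;
   5 s trials (100 samples) are tiled twice to fill one window.
4. **Classification** (`buildModel`, `trainModel`, `classify`): a
   convolutional network over the window treated as a one-channel
   time-by-sensor grid.
5. **Streaming detection** (`pushSamples`, `simulateLink`, `runSession`):
   tumbling 200-sample queues, one inference per full window, notification
   with a 450 s cooldown, and a handshake/heartbeat link model.
6. **Evaluation** (`splitDataset`, `confusion`, `classRates`, `rocCurve`,
   `loso`): stratified 60/20/20 splits, TPR/FPR/precision/recall/F1,
   trapezoidal AUC, leave-one-subject-out cross-validation with mean ± 1 SD
   outlier flagging, and per-confounder misclassification attribution.

## The synthetic gesture generator

No recorded human dataset ships with the package; every result the test
suite reports is computed on synthetic data, so the generator's design
determines what those results mean.

Each activity is a kinematic template (`gestureClasses()`): a cycle count
range (hand-to-mouth repetitions per 5 s trial), a pitch amplitude, a
raise/hold/lower/rest phase split of each cycle, a rotation signature about
the three wrist axes, and an optional superimposed oscillation (the lateral
shake of waving, the tremor of scratching). A trial renders the template as
smooth raised-cosine ramps of wrist orientation; the 9.81 m/s² gravity
vector is rotated into the sensor frame, a linear-acceleration term follows
the second derivative of hand height (damped so peaks stay in the
2–5 m/s² band of deliberate hand motion), walking superimposes a ~2 Hz gait
oscillation, and Gaussian sensor noise is added. The gyroscope emits either
angular rate (default) or the orientation angles themselves
(`gyroMode = "orientation"`), since deployed devices report both
conventions.

Participant variability is modelled by log-normal amplitude (SD 0.15 on the
log scale) and tempo (SD 0.10) multipliers and a log-normal scatter (SD
0.20) of the per-participant noise SD around the protocol baseline
(0.4 m/s² by default). The default cohort is 21 participants — the usable
cohort size after exclusions in the protocol the generator emulates — and
all three postures are available to everyone unless `postureDropProb` is
raised, in which case standing/walking may drop out (seated always remains,
mirroring comfort-limited data collection).

What the generator does **not** emulate: biomechanically validated limb
trajectories, sensor calibration drift, device orientation changes on the
wrist, free-living gesture co-occurrence, or class imbalance beyond the
protocol's 1-in-16 smoking share. Passing tests therefore demonstrate that
the pipeline's machinery is correct and that the architecture can learn
gesture structure of this kind — not field performance on human data.

Smoking is deliberately rendered distinct at the template level (slow 3–4
puff cycles, a long mouth hold, a pronounced wrist roll) from its nearest
confounders (eating: 4–6 fast shallow-hold cycles; drinking: 1–2 long-hold
cycles). The registry documents every template so reviewers can tune
realism; a nearest-centroid separability check in the test suite guards the
property that, at near-zero noise, the 2-class problem is solvable at ≥95%
accuracy — without that, downstream learning checks would be vacuous.

## Gravity separation

`g' = alpha*g + (1-alpha)*a` per axis with `alpha = 0.8` by default. From a
zero initial estimate under constant input the recursion has the closed
form `g_t = (1 - alpha^t) * a`, so the initialization transient decays like
`alpha^t` (below 1e-6 of the input by step 100 at 0.8). We initialize the
gravity estimate from the *first raw sample* of each recording
(`init = "first"`) so the head of a 100-sample trial is not contaminated by
that transient; `init = "zero"` is available and is what the closed-form
tests use. The filter is applied per recording — trials are independent —
never across recording boundaries. The filter is linear and time-invariant;
the test suite checks additivity and the exponential forgetting bound
directly.

## The classifier

```
conv(8, 5x5, leaky ReLU) -> conv(16, 3x3, leaky ReLU) -> maxpool(2x1)
-> conv(32, 3x3, leaky ReLU) -> maxpool(2x1) -> flatten
-> dense(1024) -> dropout(0.5) -> dense(K, softmax)
```

The window is a one-channel 200 x 6 grid; kernels span time and sensor axes
jointly. Design choices that were genuinely open and how we resolved them:

* **Padding**: `same` on both axes for all conv layers — a 5 x 5 kernel on a
  6-wide sensor axis would otherwise nearly exhaust it. This makes the
  parameter count reproducible: 9,839,490 for the 2-class head (the test
  suite asserts the per-layer tally).
* **Pool placement**: the two 2 x 1 time pools sit after the second and
  third convolutions, preserving full width for the 5 x 5 then 3 x 3
  kernels.
* **Optimizer**: Adam at learning rate 0.001 (the stated rate), batch 32,
  categorical cross-entropy. Adam moments are reset per `trainModel()` call.
* **Leaky ReLU slope**: 0.01, also used on the dense layer.
* **Normalization**: per-channel z-scoring with statistics fitted on the
  training windows only, persisted in the checkpoint.
* **Decision rule**: argmax (0.5 for two classes), exact ties to the lowest
  class index; ROC analysis sweeps the smoking-class probability.
* **Augmentation**: each training window is presented at a random circular
  time shift every epoch. The streaming detector's tumbling windows are
  never phase-aligned with gesture onsets, and since short trials are tiled
  periodically into windows, a circular shift introduces no boundary
  artifact. This measurably improves generalization to held-out smoking
  windows; disable with `augmentShift = FALSE`.
* **Training roles**: the 60/20/20 subsets are train / model selection /
  reporting; all numbers quoted by the acceptance machinery come from the
  evaluation subset.
* **16-class variant**: identical layers except the output width; it is
  retrained from scratch, not fine-tuned from the 2-class model.

The network, its backward pass and Adam are implemented in compiled code
(RcppArmadillo) inside the package; gradients are verified against central
finite differences on a reduced architecture, and all randomness
(initialization, shuffling, dropout, augmentation) is drawn from R's RNG so
`set.seed()` reproduces training exactly.

## Streaming detection and the device link

Samples accumulate in two queues (accelerometer, gyroscope, synchronized by
arrival index); when both reach 200 entries the window is drained
(tumbling advance) and classified. A smoking classification emits a
notification only if none occurred within the preceding 450 s — one
notification per smoking bout — otherwise a `suppressed` event is logged,
keeping every detection auditable. The cooldown is measured from
notification emission and does not restart on suppressed detections.

The watch-phone link is a state machine: greeting → acknowledgment → first
heartbeat completes the handshake and starts streaming; heartbeats arrive
every 3 s; 6 s without one ceases transfer at `last heartbeat + 6` and a
fresh handshake reconnects. During replay (`runSession`) samples arriving
while disconnected are dropped and counted, so the conservation identity
`windows*200 + buffered + dropped = pushed` holds for any input.

## Evaluation conventions

* 60/20/20 split sizes are the per-class nearest-integer rounding with the
  remainder absorbed by the training subset — at n = 1054 this reproduces
  632/211/211 exactly.
* Zero-denominator precision/recall/F1 are defined as 0.
* ROC thresholds are the unique scores plus +Inf; tied groups enter as one
  point, so the trapezoid counts tied positive/negative pairs as 1/2 and
  the AUC equals the Mann–Whitney concordance probability (the suite checks
  agreement to 1e-10 against an exhaustive pairwise oracle).
* LOSO accuracy is window-level; outliers are participants beyond mean ± 1
  SD of the per-participant accuracies.
* One-vs-rest reduction for multi-class rates; the smoking class is
  designated by name, not index.

## Problem sizes and numerical choices

The heavyweight checks run at deliberately chosen sizes: the held-out-F1
check trains the full architecture for 15 epochs on the 21-participant
cohort (1008 windows, 604 in training) at noise SD 0.05 — the low-noise
regime in which the generator guarantees separability — and the LOSO check
uses 6 participants at 20 epochs. Fifteen epochs is where the training loss
on this cohort has long plateaued (near 1e-3); more epochs do not change
the reported metrics. Softmax inputs are max-shifted before
exponentiation; probabilities are floored at 1e-12 inside the loss;
channels with zero variance get unit scale during normalization.

## Known limitations

* Synthetic-only evaluation: headline numbers here characterize the
  pipeline on its own simulator, not on human recordings; they are
  analogues, not reproductions, of field results.
* The simulator's gyroscope is derived from the same orientation trajectory
  as the accelerometer, so the two modalities are more redundant than in
  real hardware.
* The streaming detector assumes the two sensor queues stay index-aligned;
  real transports can drop channels independently.
* Single-label windows: co-occurring gestures (smoking while walking is the
  only composite, via posture) are out of scope.
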