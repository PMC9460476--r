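---
title: "Adaptive multi-day gait pattern recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive multi-day gait pattern recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftadapt)
```

## The problem

Myoelectric pattern-recognition systems for the lower limb predict the
upcoming gait activity (level walking, stair and ramp ascent/descent,
sit/stand transitions) from a short window of EMG and kinematic signals
ending just before each gait event (initial contact). Their accuracy decays
across days — *concept drift* — because electrode placement, skin condition
and fatigue change the input distribution while the classifier stays fixed.
`driftadapt` implements a complete desk-scale testbed for this problem: a
synthetic multi-day gait-session generator, the classical signal-conditioning
and time-domain feature pipeline, small mode-specific neural classifiers, and
five update policies evaluated under a streaming multi-day protocol.

## The classifiers

Both the forward (pre-step) and backward (post-stride) predictors are
single-hidden-layer rectifier networks with a softmax output, trained with
Adam (step size 0.001, mini-batches of 32) for at most 100 epochs with a 10%
random validation split. The forward predictor is *mode-specific*: one
network per current activity, each over only the successor activities
observed from that mode, so a mode with `N` reachable activities yields an
`N`-class posterior. Modes with a single observed successor get a constant
predictor (posterior 1, entropy 0); modes with too few samples to fit a
network fall back to a class-frequency posterior until their pool grows.
Features are z-scored with parameters fitted on the current training pool and
refitted at every retrain, because the raw feature blocks mix units of very
different magnitude and unscaled inputs cripple small networks.

**Early stopping.** Training stops when the validation error rate has been
strictly above its best value for 3 consecutive epochs, and returns the
weights of the most recent epoch at or below that best. We deliberately do
*not* stop when the validation error merely fails to improve: the validation
split of a few dozen samples quantises the error rate coarsely, so it
plateaus at its resolution floor long before the decision boundary has
converged, and stopping there froze badly underfit weights (11% training
error on a fixture where a nearest-centroid rule is error-free). Counting
only strictly-degrading epochs is the conventional rising-validation-error
rule and leaves plateaus free to keep training within the 100-epoch budget.

Retraining is always from scratch with a fresh seeded initialisation — the
update policies *retrain*, they do not fine-tune — and every retrain derives
its seed deterministically from the protocol seed, so whole runs are
reproducible bit-for-bit.

## The adaptation policies

Five policies share one retrain scheduler (retrain after every 2 trials):

* **baseline** — never updates; the drift-exposure reference.
* **perfect** — adds every predicted event with its ground-truth label; the
  upper reference, unavailable in deployment.
* **entropy** — self-training gated by confidence. For a posterior `p` over
  `N` classes the entropy `E = -sum(p_k log p_k)` is compared against
  `Thr(N) = 0.6 / ln(5) * ln(N)`; iff `E < Thr(N)` the event's forward
  features join the pool with the *predicted* label. The threshold is
  anchored so five classes give exactly 0.6 and scales with `ln N` so modes
  with different successor counts are gated comparably. Ties are rejected
  (strict inequality), which also makes single-class modes (`E = Thr = 0`)
  never self-select.
* **backward** — a separate 7-class network labels each completed stride
  from its mechanical summary features; that label is attached to the
  event's forward features and pooled *unconditionally*. The backward
  predictor itself stays fixed.
* **backward_entropy** — as `backward` for the forward pool; additionally
  the backward predictor's own pool grows with (stride features, predicted
  label) pairs whose backward-posterior entropy is below the threshold, and
  the backward predictor retrains on the same 2-trial schedule. The
  forward-pool update stays ungated — the entropy gate protects only the
  backward predictor's own training set.

## The streaming protocol

Each run trains on the chronologically first 50% of day-1 trials (a
chronological rather than random split preserves streaming causality; a
random split is exposed as an option) and then replays the remaining trials
in order. Every event of a trial is predicted before the trial is handed to
the policy, so no sample can enter a training pool before it has been
tested; the audit trail records the stream position of every prediction and
every pool insertion, and the test suite verifies the invariant directly.
The error rate is the number of wrongly classified samples divided by the
total, reported per day, per day-and-activity (conditioned on the *true*
label), and as a running per-trial curve. Day-to-day drift is visualised by
a PCA fitted on day-1 features only, onto which all days are projected
(per-day mean and 1-SD covariance ellipse).

## The synthetic sessions

The generator emulates the structure of a four-day recording campaign on
days 1, 2, 3 and 7: 40 repetitions per day of a fixed activity circuit
(stand up, walk, stairs up, walk, ramp down, walk, ramp up, walk, stairs
down, walk, sit down), each repetition emitting ~25 gait events (~1000 per
day, matching the observed scale of ~956 ± 70 samples per day). Each event
carries a 16-dimensional forward and a 12-dimensional backward feature
vector drawn from class-conditional Gaussians. These dimensions are
deliberately smaller than the raw-pipeline vectors (184 forward, 120
backward): the abstract generator models the classifier's *input
distribution*, not the channels, and the reduced dimension keeps the
many-retrain streaming experiments tractable while leaving the learning
problem comparably hard.

Drift is modelled as an additive per-day mean shift plus a multiplicative
covariance scale. The default shift magnitudes (0, 0.8, 1.0, 1.1
within-class SDs on days 1, 2, 3, 7) put the largest step between days 1
and 2 with a plateau after; the default variance scales (1, 0.75, 0.65,
0.65) make within-day variation largest on day 1. Shift directions point
each class toward its nearest neighbouring class mean. This choice is
deliberate: isotropic random shifts of this size are largely absorbed by
the simultaneous variance reduction and do not raise the error of a
day-1-trained classifier, whereas loss of class specificity — what sensor
displacement actually causes — moves classes toward one another. It is the
simplest mechanism that reproduces the observed qualitative pattern (error
rising sharply from day 1 to 2, then plateauing, while the feature cloud
shifts and tightens). Class means are placed at random with scale 1.0 SD
per coordinate, which puts the day-1 error of the trained system in the
mid single digits — the regime these systems operate in.

What the generator does **not** model: correlated features within a class,
non-Gaussian or multimodal class shapes, within-day drift (fatigue),
subject-to-subject structure beyond the seed, and any coupling between
forward and backward representations of the same event beyond the shared
label. Passing tests on this generator therefore show that the adaptation
machinery behaves correctly under controlled drift, not that the absolute
error levels transfer to recorded human data.

The raw-signal simulator exists to exercise the conditioning and feature
extraction stages: EMG channels are band-limited (20–450 Hz) noise carriers
amplitude-modulated by per-stride bursts, mechanical channels are smooth
class-dependent stride waveforms plus noise, and gait events are *emitted*
by the generator rather than detected from the signals, since event
detection is outside the package's scope.

## Numerical choices and degenerate inputs

* Forward windows are half-open: exactly 300 ms of signal ending one sample
  before the event, so the event sample itself is never read (causal
  prediction). Stride windows keep the most recent 1500 ms when a stride is
  longer, since late-stride mechanics are most informative for the imminent
  transition.
* Preprocessing order is resample → high-pass → MVC-normalise: filter at
  the final common rate, normalise last so references share units with the
  filtered data. The two EMG operations are linear per channel and commute,
  which the tests verify.
* The zero-crossing/slope-sign-change deadband defaults to 0; real EMG
  pipelines often use a small one, so it is configurable.
* AR coefficients use the Burg method (stable on short windows) in the
  prediction convention `x_t = sum(a_i x_{t-i}) + e_t`; perfectly
  predictable windows, whose Burg recursion degenerates, fall back to the
  highest fittable order with zero-padding. The mechanical standard
  deviation uses the population divisor `n`, consistently in forward and
  backward features.
* Pool sizes are uncapped by default (an optional FIFO cap exists because
  unbounded growth raises retraining cost); pooled samples whose
  pseudo-label falls outside their mode's fixed class list are excluded
  from that mode's retrain, and per-mode class lists stay fixed at those
  observed in the initial training data.

## Problem sizes in the shipped tests

The unit tests run on reduced sessions (1–2 days, 3–20 trials). The
end-to-end acceptance checks use the full default conditions — 4 days × 40
trials × ~25 events — with 20 seeded sessions per comparison, chosen as the
smallest replication count at which the strategy ordering (perfect ≤
entropy ≤ baseline on days ≥ 2) and the backward-adaptation benefit are
stable across re-runs of the whole suite.

## A worked example

```{r example, eval = FALSE}
library(driftadapt)

session <- simulate_feature_session(drift = drift_config(seed = 7))
baseline <- run_protocol(session, protocol_config("baseline", seed = 3))
entropy  <- run_protocol(session, protocol_config("entropy",  seed = 3))
round(rbind(baseline = baseline$per_day_error,
            entropy  = entropy$per_day_error), 3)

pd <- pca_drift(session, activity = "RAMP_ASCENT")
pd$per_day$day2$mean - pd$per_day$day1$mean   # projected drift
```

## Known limitations

The package evaluates with the true current mode taken from the stream
(as a labelled evaluation protocol does); in deployment the mode would be
the previous *prediction*, which couples errors across steps. Statistical
comparison of strategies (repeated-measures ANOVA and post-hoc tests) is
left to standard tools on the exported per-run tables. The raw-signal model
is a fixture generator, not a biomechanical simulation; absolute error
rates on synthetic data are not predictions for human recordings.
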