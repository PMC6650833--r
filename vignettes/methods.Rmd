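---
title: "Remote stress/boredom detection: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote stress/boredom detection: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what each
stage assumes, which knobs matter, what the synthetic generator does and
does not emulate, and where genuinely open design choices were settled.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Signals and features

The pipeline consumes two per-frame streams extracted from video of a
seated player: a 68-point facial landmark track (iBUG-68 layout, as
produced by detectors such as CLNF; the detector itself is out of
scope) and the spatial mean of the R, G and B channels over the facial
region. An optional 1 Hz wearable heart-rate stream provides the
sensor-based feature F9 used for comparison protocols.

**Facial features (F1–F7).** Per frame: F1 outer-lip perimeter, F2
mouth-corner distance, F3 summed shoelace area of the two eye contours,
F4 inner-eyebrow distance, F5 convex-hull area of all 68 points, F6 the
trailing one-second path length of the nose tip, F7 the frame-to-frame
displacement of the landmark centroid. These exact formulas are fixed
here as the reference definitions: each is a unit-testable geometric
proxy for the named facial behaviour (zygomatic and corrugator
activity, blinking, distance to camera, head motion). They are computed
in raw pixel units with no landmark-level normalisation — scale
differences between subjects are absorbed by the per-subject feature
standardisation inside the classifier, which is the appropriate place
for them in a user-tailored method.

**Aggregation.** A 15 s window moved in 1 s steps (93.33 % overlap)
slides over the stream. Slowly-varying features (F1, F2, F5) aggregate
with the window mean; fast-varying ones (F3, F4, F6, F7) with the
standard deviation, which responds to event density (blinks, motion
bursts) rather than posture. F7 is a movement feature, so it follows
the standard-deviation rule. We use the population (n-denominator)
standard deviation: windows hold 750 frames at 50 fps, where the n vs
n−1 distinction is negligible, but a single convention is required for
exact tests.

**Frame-0 convention.** F6 and F7 need a predecessor frame; the first
frame's value is 0.

## 2. rPPG heart-rate estimation (F8)

Blood-volume changes modulate skin colour; the pulse is strongest in
the green channel but mixed with motion and illumination in all three.
Per window each channel is linearly detrended and z-normalised, then
separated into three independent components with FastICA (symmetric
decorrelation, logcosh nonlinearity, seeded initialisation, implemented
in the package). Each component's Hamming-windowed power spectrum is
zero-padded until the bin spacing is at most 1 bpm, and searched in the
physiological band 0.75–4 Hz (45–240 bpm). The winning component
maximises the in-band peak-to-total power ratio, where "peak power" is
the power within ±2 bpm of the spectral argmax — a definition that
tolerates the leakage of the Hamming main lobe. The estimate is 60
times the peak frequency.

Numerical choices:

* **Minimum peak ratio 0.2.** White noise spreads its in-band power over
  roughly 200 bins, giving peak ratios well below 0.1, while a genuine
  pulse (even with its 0.3-amplitude second harmonic in band)
  concentrates well above 0.3; 0.2 separates the regimes with margin.
  Windows below the threshold yield a *no-estimate* result, not an
  error.
* **History constraint 12 bpm.** Heart rate cannot jump arbitrarily
  between windows that overlap by 14 s. If the raw estimate differs
  from the previous accepted one by more than 12 bpm, the next-highest
  in-band peak within range is taken; failing that, the previous value
  is carried forward flagged `accepted = FALSE`.
* **Missing-window policy.** Leading windows with no estimate ever
  produce `NA`; dataset assembly drops those windows (facial values
  included) so feature vectors are always complete.
* **Linear detrend** rather than smoothness priors: sufficient for the
  drift the generator produces and fully deterministic.

F9 needs none of this machinery: it is the mean of the 1 Hz sensor
samples falling inside the window.

## 3. Segmentation and labeling

Calibration games ramp difficulty without a stopping point, so the
session starts boring and ends stressful. The first `D = 45` s are
discarded (initial excitement and game learning contaminate the boredom
label). The remaining `R = T − D` seconds split into thirds of
`L = floor(R/3)` whole seconds: `H0 = [D, D + L)` labeled boredom,
`H1 = [T − L, T)` labeled stress, middle discarded (unknown state).
Flooring keeps H0 and H1 equal length and label-pure, with the slack
absorbed by the discarded middle; thirds are computed in seconds, and
all intervals are half-open with the window grid anchored at the
segment start. Exclusions are whole-subject for calibration problems: a
corrupted game invalidates the subject's other pairs for protocol
comparisons as well.

## 4. Testing dataset from self-reports

After each evaluation-game level the subject rates stress and boredom
on 5-point Likert scales. The level's stress score is
`rstress − rboredom` (boredom score the negation), so the scores are
antisymmetric and a level cannot be claimed by both classes. Per
subject, the two highest-scoring levels per class are selected; any
selected level with score < 1 is dropped as inconclusive. Ties break
toward the earliest-played level (deterministic and order-respecting).
If one class ends up empty the subject is unevaluable and is excluded
from cohort aggregates with a logged reason; if a class keeps a single
level, evaluation proceeds with what survives. Test samples are
windows `[t − 15, t)` ending on a 5 s grid starting at `t = 15` inside
the level — trailing windows, so every sample uses only signal from
inside the level, and consecutive samples share at most 10/15 of their
span.

## 5. The user-tailored classifier

One model per subject, trained only on that subject's calibration
windows. The network is a single-hidden-layer feed-forward classifier.
Hyperparameters are drawn by random search — hidden units from
{2, 4, 8, 16, 32, 64}, L2 weight decay log-uniform on [1e−5, 1] — and
scored by mean AUC over 10-fold stratified cross-validation repeated 3
times; the best draw is refit on all training data. Standardisation
(per-feature z-scores) is refit inside every CV fold on the fold's
training part only, and finally on the full training set, so no test
information leaks into scaling. Training uses full-batch BFGS with a
fixed iteration cap and no early stopping, which makes runs exactly
reproducible from the seed; with a second-order full-batch optimiser
there is no learning-rate hyperparameter, so the search space is
hidden-size × decay (× iteration cap). Stratified folds protect the
AUC estimate on the ~80-per-class window counts typical here.

Default search size is 30 draws. The cohort-level experiments in the
test suite and acceptance script use a reduced search (4–8 draws,
hidden sizes up to 16, 150–200 iterations) — on the well-separated or
null synthetic cohorts the reduced search reaches the same inner-CV AUC
as the full one, and it keeps a 10-subject end-to-end experiment inside
minutes on one CPU. The CV protocol itself (3×10-fold, AUC) is never
reduced.

## 6. Evaluation protocols and statistics

* **LOSOCV** (three calibration games): hold each game out once, train
  on the other two; per-subject accuracy `A_i` is the mean of the three
  fold accuracies `L_j`; pooled fold accuracies form the sample for
  paired protocol comparisons.
* **Cross-game**: train on all three calibration games, test on the
  self-report-labeled evaluation samples; the cohort aggregate is the
  mean `A_i` over evaluable subjects.
* **Metrics**: confusion-matrix accuracy, per-class precision, recall
  and F1 with macro averages; undefined ratios report 0 (a subject
  whose model never predicts a class genuinely has zero precision
  there).
* **Chance level**: for `X ~ Binomial(n, 1/c)`, the threshold count is
  the 1−α quantile of X — the smallest k with `P(X ≤ k) ≥ 1 − α` — so a
  guesser beats it with probability at most α. Reported exactly and
  floored to integer percent; at n = 64, α = 0.05 the exact value is
  60.94 % and the floored, conventionally printed figure is 60 %.
* **Wilcoxon signed-rank**: zero differences dropped; for ≤ 15 pairs
  the two-sided p-value is exact (signed-rank null distribution when
  the absolute differences are tie-free, exhaustive sign-flip
  enumeration otherwise); larger samples use the tie-corrected normal
  approximation with continuity correction. Effect size `r = |Z|/√N`.
  Two-sided p-values are reported with a one-sided column for
  pre-stated directional hypotheses.

## 7. The synthetic-data generator

The generator emulates the *statistical structure the method assumes*,
with known ground truth:

* **Heart rate** is an Ornstein–Uhlenbeck process reverting (rate
  0.5 /s, stationary sd 1.5 bpm) to the scheduled state's mean — 70 bpm
  in boredom vs 90 bpm in stress at full effect.
* **Pulse** `sin(2π∫f dt)` plus a 0.3-amplitude second harmonic is
  injected into the RGB baseline with green-dominant amplitudes
  (R:G:B = 0.3:1.0:0.6), plus white noise (sd 0.3 pixel values) and
  Poisson step artifacts.
* **Landmarks** start from a frozen synthetic neutral face template and
  undergo a mildly anchored rigid random walk (state-scaled step),
  Poisson blinks (0.25/s boring, doubled under stress) collapsing the
  eye contours over 300 ms, and Poisson mouth/brow events over 500 ms.
* **Sensor HR** samples the true trajectory at 1 Hz with ±1 bpm jitter.
* **Self-reports** follow the evaluation-game design (levels 3 and 6
  stressful, 4 and 7 boring, others mixed): a stressful level draws
  rstress from {4, 5} and rboredom from {1, 2}, and conversely, with a
  5 % confusion probability.

A single `effect` knob in `sim_profile()` scales the state contrast
from null (identical states) to the full ΔHR = 20 bpm / doubled-rates
profile, which is what the graded parameter-recovery experiments vary.
Default session lengths are 165 s per calibration game (giving 26
windows per H0/H1 segment, 156 training windows per subject) and 90 s
per evaluation level (giving 16 test samples per selected level, 64 per
subject with two levels per class — matching the test-set size at which
the chance level is calibrated).

What the generator does **not** emulate: real facial-expression
dynamics (only rates change between states, not expression content),
illumination changes, skin-tone diversity, landmark-detector error
correlated with pose, or self-report biases beyond symmetric confusion.
Passing tests therefore demonstrate that the pipeline recovers the
states *its own assumptions describe* — a necessary correctness bar,
not evidence about human recordings.

## 8. Known limitations

* The rPPG chain is the ICA/spectral-peak family; chrominance-model and
  ballistocardiographic methods are out of scope.
* The classifier family is deliberately small; deep or recurrent
  models, and group-level (cross-subject) training, are non-goals — the
  method's premise is user-tailored models.
* Headline accuracies reported for human cohorts in the literature
  cannot be reproduced without the original recordings; the package
  substitutes property-based synthetic experiments (strong-effect,
  null, and graded-effect cohorts) that test the same machinery end to
  end.
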