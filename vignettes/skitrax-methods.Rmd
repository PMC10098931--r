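---
title: "Methods: from key-point trajectories to ski sub-technique labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from key-point trajectories to ski sub-technique labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skitrax)
```

# The problem and the processing model

A trackside camera and a pose estimator deliver, per video frame, the
image (or lifted 3D) coordinates of a skier's anatomical landmarks and
pole tips, each with a confidence. The goal is to decide which
sub-technique — double poling (DP), diagonal striding (DS) or the
downhill tuck (DT) — each motion cycle belongs to. The three techniques
are separated by their *interlimb coordination*: DP moves both elbows
and knees in phase and plants both poles together; DS alternates them
with a half-cycle offset; DT holds nearly constant tucked joint angles
and never plants the poles.

The pipeline is: gap filling of dropped key points, low-pass smoothing
of each trajectory channel, valley-based cycle segmentation of the ankle
trajectory, extraction of 13 waveform descriptors per channel, center
standardization, and a support vector machine. Every stage is an
ordinary, auditable computation; the only fitted object is the SVM (plus
its standardizer), returned as a classed `ski_recognizer` with `print`,
`summary` and `predict` methods.

# Skeleton schema

The default schema has 17 body points — seven left/right pairs (temple,
shoulder, elbow, wrist, hip, knee, ankle) plus head, neck and mid-hip —
and the two pole-tip points. Published descriptions of this taxonomy
enumerate only the seven pairs while stating 17 anatomical points; the
head/neck/mid-hip completion used here is the smallest set that supports
a root (head–neck) feature and a pelvis center, and the schema is fully
user-configurable, so any other 17-point reading can be loaded without
code changes. Angle triplets (proximal, vertex, distal) default to the
left/right elbow and knee.

# Detection mathematics

The detection module is *reference math*, not a detector: it exists so
that the arithmetic a joint person/key-point detector relies on can be
verified independently of any trained network.

* **Anchor decode.** `bx = (2σ(dx) − 0.5) + AKx` (likewise y),
  `bw = AKw·e^dw`, `bh = AKh·e^dh`. The bounded offset keeps the decoded
  center within (AK − 0.5, AK + 1.5), which the tests assert. Person
  anchors default to a 1:4 width:height family — (12, 20), (26, 46),
  (43, 102) at stride 8 — because standing skiers are tall boxes.
* **Losses.** Three components: summed binary cross-entropy over class
  scores; objectness BCE on sigmoided logits averaged over the number of
  targets (defined as 0 with a warning when there are no targets); and a
  mean squared box error in which σ is applied to the raw center offsets
  *but not* the `2σ − 0.5` decode — the loss is implemented exactly as
  defined even though it differs from the inference-time transform, and
  the discrepancy is deliberate fidelity, not an oversight. The weighted
  total uses balancing coefficients (0.6, 0.2, 0.3). Published
  descriptions of this loss family attach the names "category",
  "confidence" and "location" inconsistently to the three symbols; the
  implementation therefore binds weights to *components* (class, box,
  objectness) via explicit argument names so either reading is
  reproducible by reordering arguments.
* **NMS** is greedy and class-wise by default (a `class_agnostic` flag
  switches it), keeps the highest score, and breaks exact score ties by
  input order, which makes the survivor set order-independent for
  distinct scores.
* **Fusion** assigns, per person box and key-point class, the detection
  whose center minimizes the Euclidean distance to the box center;
  distance ties keep the earlier detection. An empty person list is an
  error: without a candidate region there is nothing to fuse into.
* Log arguments are clamped at `1e-12` so degenerate probabilities never
  produce infinities.

# 3D tools

* **Rotation compensation.** `R = Rx·Ry·Rz` about fixed (extrinsic) axes
  in that written order; the loss is the mean squared Frobenius distance
  to the ground-truth rotation. Whether the square denotes Frobenius
  norm or an elementwise sum is immaterial — they are the same number —
  and the tests pin the convention.
* **Position loss** is the mean squared per-joint offset norm. (The
  circular printed form of this quantity in the source literature —
  defined in terms of itself — admits only this standard reading.)
* **Gap filling.** A key point missing in one frame, observed in the
  nearest previous and next frames, is filled with the coordinate-wise
  midpoint `(x0 + x1)/2`. The halved *difference* `(x1 − x0)/2`
  sometimes printed for this rule returns 0 for a stationary landmark —
  impossible for a position — so the midpoint is the default and the
  printed form survives only behind `strict_halved_difference = TRUE`
  for auditability. Longer gaps use an ordinary least-squares line per
  coordinate over a 5-frame window each side: at ≥ 50 Hz the inter-frame
  motion is close to linear, which is what makes a linear fill accurate.
  Gap filling never touches observed frames, and gaps without enough
  support are left missing rather than guessed.
* **Joint angles** are `arccos` of the normalized inner product of the
  two limb vectors at the vertex, clamped to [−1, 1], reported in
  degrees in [0, 180]; degrees externally, radians internally. A
  zero-length limb is an error, and missing members propagate missing
  angles.

# Smoothing

Two smoothers, composable:

* **EM local-level smoother.** The literature this package follows
  invokes "EM parameter estimation" for jitter suppression without
  stating a model. The minimal model consistent with that purpose is the
  per-channel local-level state-space model `y_t = μ_t + ε`,
  `μ_t = μ_{t−1} + η`, with the two noise variances estimated by EM
  (Kalman filter/smoother E-step with lag-one covariances; closed-form
  variance M-step) and the posterior state means as output. The
  log-likelihood trace is returned and asserted non-decreasing on every
  fit. Initialization splits the variance of the first differences
  between the two noises; the initial-state prior spread is held fixed
  at the sample variance. Variances are floored at `1e-12`; constant
  input would degenerate the observation variance and is returned
  unchanged with a warning. On noiseless data EM approaches the
  zero-observation-noise fixed point only asymptotically, so "exact"
  recovery claims are tested as small bounds (≤ 1e-3 on a range-10 ramp
  after 200 iterations), not equalities. EM smoothing is off by default
  in the pipeline: the Butterworth stage below already suppresses
  detector jitter, and the EM fit is two orders of magnitude slower.
* **Zero-phase Butterworth.** The analog squared magnitude
  `1/(1 + (ω/ωc)^{2n})` has unit DC gain, exactly ½ at the cutoff for
  every order, and is monotone — all asserted. The digital realization
  uses `signal::butter` (bilinear transform with pre-warped cutoff) run
  forward and backward: zero phase means valley frames are not delayed,
  at the cost of squaring the gain (doubling stopband attenuation),
  which is the right trade for pole finding. Defaults are order 3 and
  14 Hz: lower orders leave jitter, higher orders flatten genuine
  valleys. Reflective (point-symmetric) padding of ~90 samples per end
  absorbs the IIR startup transient; a DC input passes through to
  ~1e-15. Single-pass mode is available (`zero_phase = FALSE`).

# Cycle segmentation

Foot landings are valleys of the ankle forward coordinate once its
linear trend (the skier's net advance) is removed; pole plants are
valleys of the pole-tip vertical coordinate. Both channels run through
the same machinery:

1. `detect_valleys`: local minima with topographic prominence of at
   least 10% of the track's peak-to-peak range (plateau minima report
   their central frame; endpoints are never valleys).
2. `merge_valleys`: adjacent valleys closer than 60 frames are combined
   into the deeper one (ties keep the earlier); the operation is
   idempotent and its output has all gaps ≥ 60 frames.
3. `segment_steps`: one step per consecutive valley pair, with the pixel
   step (absolute track difference), the Euclidean variant, and
   duration = frames / fs.
4. `filter_steps`: the first and last segments are dropped (incomplete
   by construction); interior steps more than 50 px below the median
   pixel step are removed. The alternative literal reading of that rule
   — removing steps *within* 50 px of the median — would delete every
   typical step and is not provided. Steps spanning fewer than 150
   frames are flagged, not dropped: at 60 Hz a 0.9 Hz cycle is ~67
   frames, so the 150-frame "complete phase" floor describes multi-step
   phases, and enforcing it as a hard filter would empty every sequence.
   Both the 60-frame merge gap and the 150-frame floor are expressed in
   frames (as stated), with the frame rate recorded so callers at other
   rates can rescale.

`backward_diff` (first element defined 0 so lengths match and the
cumulative sum reconstructs the input) supports derivative-based
detection as an alternative.

# Features and classification

Each analysis window yields 13 descriptors per channel: Max, Min, mean,
peak-to-peak, standard deviation (with 1/n inside the root), kurtosis
(denominator `(n−1)·st⁴`), skewness (denominator `n·st³`), RMS, shape
factor RMS/mean|x|, crest factor pk/RMS, and the periodogram moments FC
(centroid), MSF (second moment) and VF (variance about the centroid).
The non-textbook 1/n vs (n−1) mixtures are implemented exactly as
defined — they are the feature definitions, not estimators to be
"corrected" — and VF ≡ MSF − FC² is asserted as an identity. For a
constant channel (st = 0, typical of DT) kurtosis and skewness are
returned as 0 with a degeneracy flag rather than raising, so static
techniques flow through the pipeline. The PSD is the mean-removed
one-sided periodogram scaled so total power equals the population
variance (discrete Parseval); a Hann window is available but
rectangular is the default since the descriptors are moments, not peak
estimates.

**Channel set.** The eight base channels are the left/right ankle
forward coordinates, left/right pole-tip vertical coordinates, and
left/right elbow and knee angle series. Two derived channels are
appended by default: the left-minus-right elbow angle and the
left-minus-right ankle forward coordinate. The reason is structural:
all 13 descriptors are marginal statistics of a single channel, and a
half-period phase shift — the *defining* difference between DP and DS —
leaves every marginal statistic of a periodic waveform unchanged. The
bilateral difference channel converts that phase relation into
amplitude: near zero for in-phase DP, a full-swing oscillation for
anti-phase DS, near-constant for DT. Bilateral asymmetry measures of
this kind are standard in gait analysis. The channel list is fully
configurable.

**Granularity.** Features are computed per sequence over the span of
the retained cycles by default (one labeled group per recording, the
granularity at which corpus counts like 79/66/75 are quoted, and the
one that keeps cross-validation free of within-sequence leakage);
`granularity = "cycle"` computes one vector per retained step instead.
A model must be applied at the granularity it was trained on — the
descriptor distributions of a 60-frame cycle and a 400-frame span
differ.

**Classifier.** Center standardization (per-feature z-score; parameters
learned on the training split only and stored in the model; zero-
variance features map to 0) followed by an SVM. The kernel form is
generic, so the package defaults to RBF with the standard 1/d bandwidth
and exposes a linear option. Multi-class handling and score calibration
use libsvm's native one-vs-one scheme with Platt-scaled, pairwise-
coupled probabilities — the field-standard route to calibrated scores
in [0, 1] — rather than a hand-built one-vs-rest sigmoid stack. A KNN
model (k = 5, Euclidean, vote fractions) rides along for optional score
fusion (the plain average of the two score vectors; exact ties fall
back to the SVM's label); fusion is off by default because the primary
pipeline description is SVM-only. Cross-validation is stratified k-fold
(default 5) on a 90% pool with a 10% stratified holdout evaluated once;
standardization is refitted inside every fold.

# Evaluation metrics

PCK here is the bare ratio of detected to ground-truth key points —
deliberately *without* the distance threshold other PCK definitions
use; a thresholded variant exists behind explicit arguments. MPJPE is
the per-frame mean Euclidean distance over jointly observed joints
(missing joints excluded pairwise, counts reported), averaged over
frames. MAEA is the symmetric mean absolute angle difference in
degrees.

# The synthetic kinematics generator

The simulator exists so every stage has ground truth. Joint angles
follow sinusoids: elbow 60–160° and knee 90–160° for DP/DS (midpoint ±
half-range), 85 ± 3° and 100 ± 3° for DT; limb positions come from a
fixed-proportion two-segment limb model driven by those angles plus a
thigh/arm swing, which makes every bone length constant to machine
precision (asserted at 1e-9). The left/right phase offset is 0 for DP,
π for DS (legs contralateral to arms), and the amplitudes collapse for
DT. Pole tips are clamped to the ground during the plant half-cycle —
synchronously for DP, alternately for DS, never for DT. The skier
advances at 2 px/frame at 60 Hz with a 0.9 Hz cycle; a 10 s recording
holds ~9 cycles. Knee flexion lags the thigh swing by a quarter cycle
(as in gait), which also guarantees the ankle's periodic component has
a single minimum per cycle.

Ground truth includes the exact angle series, the dropout log, and the
cycle boundaries: the frames at which the left-ankle periodic component
attains its per-cycle minimum, *restricted to landings with enough
in-view context to realize the 10%-of-range prominence on both sides*
(the margin is computed from the waveform itself). A landing two frames
from the clip edge has no realized valley, and no detector — this one
or any other — can credit it; excluding it makes "segmentation recovers
the generator's cycle count exactly" a well-posed claim, which the
tests then verify across techniques and phases.

`corrupt` adds i.i.d. Gaussian jitter (default sd 2 px) and independent
per-observation dropout (default 2%), seeded and logged.
`generate_dataset` draws per-sequence perturbations — cycle frequency
±15%, amplitude ±10%, speed ±15%, uniform — and a uniform random
initial phase, because real clips start mid-cycle; the manifest records
every draw, and the corpus is bit-reproducible from its seed.

**What the simulator does not emulate** — and therefore what passing
tests do and do not show: there is one synthetic athlete morphology and
one camera scale, no occlusion structure (dropout is independent, not
burst-like), no terrain or fatigue drift, and noise is Gaussian rather
than heavy-tailed detector error. Consequently the classification task
is easier than on real video: the default corpus is separated
essentially perfectly by the featurized pipeline — and, notably, also
by the raw resampled-series baseline, so the synthetic corpus
demonstrates that feature extraction *loses nothing*, not the size of
its real-data advantage (on small corpora of ~20–30 sequences the raw
baseline does drop markedly while the descriptors do not, which is the
expected direction). High synthetic accuracy validates the plumbing and
the separability logic, not field performance.

# Numerical choices and problem sizes

Tie-breaks are everywhere "first occurrence wins" (NMS, fusion, valley
merging at equal depth, fused-score ties fall back to the SVM).
Probability clamps are 1e-12; EM variance floors 1e-12; angle-cosine
arguments clamped to [−1, 1]; orthonormality and bone-length assertions
at 1e-12 and 1e-9. CSV output carries 10 significant digits; JSON
output 17 (bit round-trip). The test suite exercises the full study
corpus (220 sequences of 600 frames at 60 Hz) once and memoizes it;
property suites use 100–1000 random cases per invariant at fixed seeds;
the label-permutation control uses 20 reshuffles. The whole suite runs
in a few minutes on one CPU.

# Known limitations

The recognizer is single-athlete per clip and assumes the default
19-point taxonomy for channel extraction (the schema is configurable,
but the channel map names specific landmarks). Segmentation assumes
net forward progress in the ankle channel (it detrends linearly);
treadmill data would need the derivative-based alternative. The EM
smoother models a random walk, which over-smooths strongly periodic
signals if used with many iterations. Real-data performance claims are
out of scope: no trained detector or lifting network ships with the
package, and the evaluation metrics exist to score such systems when
their output is available.
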