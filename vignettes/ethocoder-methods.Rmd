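---
title: "Methods: two-stream features, sequence classification and confidence-based review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stream features, sequence classification and confidence-based review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ethocoder)
```

`ethocoder` labels every frame of laboratory behavior video with one of K
mutually exclusive behaviors, estimates how trustworthy those labels are, and
prioritizes which clips a human should re-check. This vignette explains the
model and the choices behind each stage; the README shows a worked run.

## Data model

A project is a set of videos, each divided into fixed-length **clips**
(default 60 s) that tile the frame range `[0, n_frames)` exactly — a trailing
partial clip is kept rather than discarded so no frame is ever lost. Frame
coordinates are 0-based and half-open everywhere; bout intervals appear only
at the CSV boundary. The clip is the atomic unit: annotation, training,
confidence scoring and review all operate on whole clips, because a reviewer
needs the context of a full clip to judge any frame in it.

Simulating partial annotation works by drawing a labeled fraction
`prop_labeled` of clips (`max(1, round(prop_labeled * N))`, rounding half away
from zero so splits are never empty), holding out `prop_validate = 0.2` of the
labeled clips for validation, and treating the unlabeled remainder as the test
set. The standard sweep `prop_labeled_grid()` uses steps of 0.02 up to 0.20 —
where accuracy responds most steeply to added annotation — and 0.05 from 0.25
to 0.90 (24 values). All splits are reproducible from a single integer seed
via named RNG substreams, so identical seeds give bit-identical pipelines.

## Two-stream features

**Spatial stream.** Raw frames are resized to 224×224, expanded to three
channels and standardized with the usual natural-image channel statistics,
then passed through an 18-layer residual convolutional backbone; the
global-average-pooling activations give one 512-vector per frame.

The packaged backbone uses seeded He-initialized weights rather than
pretrained ones: feature extraction here is a fixed measurement device, the
random network is deterministic given its seed, and random convolutional
features preserve enough image structure for the downstream classifier on the
synthetic fixtures the package ships with. Externally trained weights can be
substituted through the same structure; nothing downstream changes.

**Temporal stream.** Dense optical flow between consecutive frames is
estimated with the duality-based TV-L1 algorithm (total-variation
regularizer, L1 data term) on a coarse-to-fine pyramid. Parameters follow the
reference implementation defaults (`tau = 0.25`, `lambda = 0.15`,
`theta = 0.3`, 5 warps, up to 5 scales with zoom 0.5, inner loop capped at 50
iterations or a mean-square update below `0.01^2`). Two numerical points
matter:

* intensities are scaled to the 0–255 range internally — the standard
  parameter values assume 8-bit intensities, and with `[0,1]` inputs the
  proximal steps are two orders of magnitude too small to converge;
* flow is computed on luma (grayscale) frames; color inputs are converted.

Each flow field is rendered as an image: hue encodes orientation on a cyclic
wheel, brightness encodes magnitude clipped at a per-video constant
`max_magnitude` (default: the 99th percentile of sampled magnitudes, so
brightness is comparable across frames of one video), saturation is maximal,
and zero motion is black. The flow image for frame *t* is stacked with its
five predecessors and five successors along channels (33 channels total;
boundary frames replicate the first/last flow image), and the backbone's
first 7×7 convolution kernel is tiled 11 times along its input-channel axis
to accept the stack — every other weight is untouched, so a stack of 11
identical images reproduces (11×) the original first-layer response.

**Fusion and reduction.** Per frame, spatial and temporal 512-vectors are
concatenated camera-major (1024 columns for one camera, 2048 for two
synchronized cameras), then reduced back to 512 dimensions with
reconstruction independent component analysis. RICA learns a linear map
`W (d_in × d_out)` minimizing, over column-standardized inputs,

$$J(W) = \frac{1}{N}\sum_i \left[\lambda\,\lVert WW^\top x_i - x_i\rVert^2
        + \textstyle\sum_j \log\cosh(w_j^\top x_i)\right],$$

balancing reconstruction fidelity against independence (sparsity) of the
projections. Both terms are averaged over the N training rows; an
un-normalized penalty would dominate as N grows and drive W toward zero,
destroying the reconstruction property. The smooth unconstrained objective is
minimized by L-BFGS from a seeded random initialization (`lambda = 1`,
iteration cap 100 by default); the analytic gradient is finite-difference
checked in the test suite, and on tiny problems the attained objective agrees
with a multi-restart derivative-free optimizer to well under 1%. The
transform is fitted on the labeled clips only, so no information leaks from
the test set; a config switch (`rica$fit_on = "all"`) relaxes this.

## Sequence classifier

Clips are cut into **15-second sequences** (`round(15 * fps)` frames, plus a
shorter remainder that reconstructs the clip exactly) to limit overfitting
and padding. The network is: sequence input (512) → BiLSTM → dropout 0.5 →
BiLSTM → dropout 0.5 → per-frame fully-connected(K) → softmax, with
cross-entropy loss over K mutually exclusive classes. Each BiLSTM layer has
128 units per direction by default (the value is config-exposed; tests use
smaller layers). Within a minibatch, sequences are padded to the longest
member; padded frames are masked out of both the loss and the recurrent
state, and the forward and backward directions each process the sequence from
their own end so padding never contaminates a real frame's state.

Training uses Adam with the stepped schedule: initial learning rate 1e-3,
multiplied by 0.1 every 4 epochs, minibatch size 8, at most 16 epochs.
The validation loss is evaluated every epoch; once it has been **greater than
or equal to the smallest previous validation loss more than twice**, training
stops (epoch 1 establishes the running minimum, equality counts against
patience), and the parameters from the best-validation epoch are restored.
Minibatches mix sequences across clips and are reshuffled each epoch from the
run seed; dropout masks are drawn from a named substream, so training is
reproducible end-to-end. Unweighted cross-entropy is used deliberately: rare
behaviors are not up-weighted.

At inference, dropout is disabled, each clip is processed by the same 15-s
sequence rule and re-concatenated, giving per-frame logits, softmax
probabilities (rows summing to 1) and argmax labels.

## Confidence and calibration

The per-frame confidence is the **max softmax score**
$\hat p_j^{SM} = \max_k \sigma(z_j)^{(k)}$. Because softmax outputs of
trained networks are typically overconfident, a scalar **temperature** T is
fitted on the validation clips by minimizing the negative log likelihood of
$\sigma(z_j / T)$ — a deterministic 1-D minimization over
$\log T \in [\log 0.05, \log 20]$ — giving
$\hat p_j^{TS} = \max_k \sigma(z_j/T)^{(k)}$. T > 1 softens confidences;
predicted labels are unchanged for any T > 0.

Clip confidence is the arithmetic mean of its frame confidences; clip
accuracy the fraction of correct frames; dataset-level scores are
frame-count-weighted means over clips. Calibration is summarized per clip by
the prediction error `PE = conf − acc` and absolute error `AE = |PE|`, and
per dataset by their unweighted means MAE and MSD. Note the asymmetry, kept
exactly as defined: MAE/MSD average over clips un-weighted, while dataset
confidence weights by frame count.

## Confidence-based review

Reviewing a clip corrects it, so after reviewing the first k clips of an
ordering the dataset accuracy is
$\mathrm{acc}(D_k) = |D_k^{rev}|/|D| + \mathrm{acc}(D_k^{unrev})\,|D_k^{unrev}|/|D|$
with frame-count weights. Three orderings matter: ascending confidence (the
product feature), ascending true accuracy (the optimal bound), and random
(the no-information baseline, computed exactly by enumeration below 7 clips
and otherwise as a seeded Monte-Carlo mean over 100 orderings by default —
clip sizes may be unequal, so no closed form is assumed). The improvement
over random $IOR_k$ is the pointwise curve difference; its mean divides the
(n+1)-term sum over k = 0..n by n, exactly as defined. **Review efficiency**
is the ratio of mean IORs, candidate over optimal: 1 when confidence sorts
clips exactly like accuracy, 0 in expectation for an uninformative score,
negative for an anti-informative one. Ties in confidence are broken by clip
id so orderings are deterministic.

One subtlety: because review accuracy is frame-weighted, a clip's review gain
is `(1 − acc) × size`. The ascending-accuracy ordering is therefore provably
optimal at every k only when clips have equal frame counts; with unequal
sizes it remains the natural reference (and the one used throughout) but a
size-aware ordering can dominate it slightly. The exhaustive dominance
property in the test suite is checked on equal-size instances for this
reason.

## Synthetic generators

The generators emulate the *structure* of real behavior datasets so every
stage is testable without external data:

* **Labels**: a first-order Markov chain with per-behavior self-transition
  probability `p_stay` (mean bout length `1/(1 − p_stay)` frames); class
  imbalance arises from unequal bout lengths across behaviors — with a
  uniform `p_stay`, flow balance pins two-class chains at 50/50 occupancy no
  matter how switch targets are weighted, so dominant behaviors are modeled
  as long-bout behaviors (`stationary_weights()` gives the exact occupancy).
  Defaults `p_stay = 0.9`.
* **Video**: a band-limited texture translating with the active behavior's
  velocity kernel (plus jitter), carrying a bright blob; a zero-velocity
  behavior yields a static scene, so TV-L1 on the output recovers the kernel
  velocities — this links the video, flow and feature stages in tests.
* **Features**: class-conditional Gaussians in 512 dimensions with
  equidistant class means (pairwise distance `delta`) and isotropic noise
  `sigma` — the idealized counterpart of reduced CNN features.
* **Calibrated logits**: posteriors drawn with an exchangeable peak that is
  swapped onto the known label exactly when a class sampled *from the
  posterior* matches it. This makes the emitted probabilities exactly
  calibrated for the given labels, with argmax accuracy converging to
  `base_accuracy`; multiplying the log-posteriors by s > 1 manufactures
  overconfidence whose fitted temperature is s.

What the generators do **not** emulate: photorealistic animals, appearance
variation that challenges a pretrained backbone, annotation noise, label
co-occurrence, or long-range temporal dependencies beyond first-order
Markov structure. Passing tests therefore demonstrate that the machinery is
correct and recovers planted structure — not that any particular accuracy
will transfer to real video.

## Problem sizes and numerical choices in the test suite

The suite exercises realistic interfaces at desk scale, chosen once:

* classifier recovery: a 267-clip project of one-minute clips at 4 fps,
  `prop_labeled = 0.3` (80 labeled → 64 train / 16 validate), Δ = 6σ, K = 3,
  `p_stay = 0.9`, hidden units 32, accuracy measured on a 10-clip sample of
  the unlabeled pool, median over 3 seeds;
* the end-to-end video pipeline test uses 2 videos × 60 frames at 64 px —
  the backbone is fully convolutional, so the 512-d contract is
  size-independent and the dimension checks use full 224-px inputs;
* temperature recovery and calibration use 8–10k frames in 100-frame clips;
* flow oracles use 96-px band-limited textures with known shifts.

Degenerate inputs are handled explicitly: empty splits are impossible by the
rounding floor; single-class training labels warn and proceed; a class with
no predicted (or true) frames scores precision/recall/F1 of 0 with a
`degenerate` flag while still entering the K-class macro mean; review
efficiency is flagged undefined when no ordering can beat random (all clips
equally accurate); temperature fitting falls back to T = 1 if the bounded
search cannot improve on it.

## Limitations

* The packaged backbone is not pretrained; absolute accuracies on real video
  will not match those obtainable with ImageNet weights, though every
  interface accepts a externally constructed backbone of the same structure.
* TV-L1 and the CNN forward pass are pure R: correct and deterministic, but
  not fast enough for hours of video — the design target is method fidelity
  and testability at desk scale.
* Only feature-level fusion of synchronized cameras is supported, and labels
  are mutually exclusive per frame by construction.
* The review simulation assumes a reviewed clip becomes perfectly correct.
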