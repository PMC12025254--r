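---
title: "DU-former: model, preprocessing and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DU-former: model, preprocessing and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duformer)
```

This vignette describes the science implemented by the package: the
DU-former network for binary classification of EEG segments, the
preprocessing pipeline that produces its inputs, the synthetic EEG
generator used to validate the whole stack offline, and the choices made
where the design was genuinely open.

## The classification problem

The package targets pre/post-intervention discrimination of resting EEG:
two recordings per subject (sessions labelled `pre` and `post`, or T1 and
T5), 16 channels at the standard 10-10 sites Fp1, Fp2, F7, F8, F3, F4, Fz,
FCz, C3, C4, Cz, P7, P8, Pz, O1, O2. Continuous recordings are decomposed
into seven canonical frequency bands — Delta (1–4 Hz), Theta (4–8),
Alpha1 (8–10.5), Alpha2 (10.5–13), Beta1 (13–20), Beta2 (20–30), Gamma
(30–50) — and sliced into 2 s windows with a 1 s step (50 % overlap), so
every model input is a 16 × 2000 matrix (2 s at 1000 Hz). One model is
trained per band; comparing bands localizes where in the spectrum the
class difference lives.

## The DU-former network

The architecture composes three stages.

**Dual-branch convolution.** Both branches share the printed kernel
shapes: a 1 × 25 temporal convolution along the time axis followed by a
16 × 1 spatial convolution that collapses the electrode axis. The large
branch applies its temporal kernel with a stride (`stride_large`, default
5) that sets the token count, then batch normalization and ReLU. The small
branch runs at a finer stride (`stride_small`, default 1), applies ReLU,
then an adaptive max-pool whose window boundaries are solved so its token
count exactly matches the large branch for any input length, then layer
normalization. The branch outputs are fused by elementwise sum (a
concatenation + projection variant is available behind `fusion =
"concat"`). Internally the two stacked convolutions of a branch are
contracted into a single combined kernel — the composition is exact, and
the factorized parameterization (temporal and spatial kernels) is
retained; the temporal bias is omitted because a time-constant shift is
absorbed by the spatial bias.

**Separable-attention encoder blocks.** Two Transformer encoder blocks
follow. Attention is the separable multi-head form: per head, a scalar
projection of each token is softmax-normalized over tokens into context
scores, the context vector is the score-weighted sum of the K rows, and
each output token is the gated V row modulated elementwise by that context
vector — cost linear in the token count, with no token × token matrix. The
gate on V is ReLU by default (the convention of the separable-attention
family this design follows); a sigmoid gate is available via
`attention_gate`. Residual placement is pre-norm (`y = x + SMHSA(LN(x));
z = y + FFN(LN(y))`), chosen for training stability; the feed-forward
network is two linear layers with a ReLU and expansion ratio 4.

**Gaussian reparameterization head.** After the encoder, a mean branch
(token-axis convolution, average pooling over tokens, layer normalization)
produces μ and a variance branch (average pooling, layer normalization)
produces σ. Because layer normalization can emit negatives and σ must be a
standard deviation, σ passes through a softplus plus a floor of 1e-4. At
each training iteration a fresh ε ~ N(0, I) gives the sampled embedding
S = μ + ε ⊙ σ, which feeds a linear softmax classifier. At inference the
deterministic mode S = μ is the default; Monte-Carlo mode resamples ε.
The training loss is cross-entropy plus λ·KL(N(μ, diag σ²) ‖ N(0, I)) with
λ = 1e-4 by default; λ = 0 recovers plain cross-entropy, and the KL term
prevents σ from collapsing to the floor. Modelling the embedding as a
distribution rather than a point is a data-uncertainty (aleatoric) device:
noisy segments map to high-σ embeddings, and the noise injection acts as a
regularizer.

The two ablation switches mirror the published ablation: `use_smhsa =
FALSE` removes the attention sublayer (residual FFN blocks remain), and
`use_reparam = FALSE` feeds the pooled deterministic encoder feature
straight to the classifier.

**Training protocol.** The optimizer, learning rate, epochs and batch size
are not fixed by the architecture, so the package exposes them
(`train_hyper()`): Adam at 1e-3, minibatch 16–32, early stopping on a 10 %
validation split carved from the training data, best-validation weights
restored, and a plateau schedule that halves the learning rate after two
epochs without validation improvement. When cross-validation is
subject-wise the validation split holds out whole subjects too, so early
stopping tracks cross-subject generalization rather than within-subject
fit. Optional decoupled weight decay exempts biases and normalization
parameters.

## Preprocessing pipeline

Stage order is fixed as: broadband band-pass → ocular artifact removal →
myogenic suppression → bad-channel interpolation → band decomposition →
segmentation, and every run logs each stage with its parameters. Whether
artifact removal preceded band division in the original protocol is
ambiguous; this order is the physically sensible one (artifacts are
broadband, so removing them once before splitting avoids seven redundant
decompositions) and is recorded as a package decision.

* **Filtering** is a 4th-order Butterworth band-pass (0.5–50 Hz broadband;
  the seven band definitions for decomposition), applied forward–backward
  for zero phase, which doubles the effective magnitude order (≈48 dB one
  octave above the cutoff instead of 24). Filters are designed in
  zero-pole form and run as cascaded biquads: transfer-function
  realizations of an 8-pole band-pass at Delta-band normalized frequencies
  are numerically unusable, while individual biquads are stable. Edges are
  padded by odd reflection scaled to the filter's low-frequency time
  constant.
* **Ocular artifacts**: the recording is decomposed with a seeded
  symmetric FastICA (logcosh contrast, 500-iteration cap, tolerance 1e-6,
  as many components as channels); components whose absolute Pearson
  correlation with a supplied EOG-like reference trace exceeds 0.8 are
  zeroed before back-projection. On signals that are close to Gaussian the
  contrast has no unique optimum and the iteration may hit its cap without
  formally converging; the decomposition is still an exact invertible
  linear transform, so thresholded removal remains valid, and the status
  is flagged (`"max_iter"`) in the report rather than aborting the stage.
  Only a degenerate (non-finite) decomposition leaves the recording
  untouched.
* **Myogenic artifacts**: template matching against muscle-activation
  patterns is replaced by a transparent spectral criterion — ICA
  components with more than 60 % of their power above 30 Hz are zeroed.
  This is a simplification and is documented as such.
* **Bad channels** are taken as explicit user input (impedance-based
  detection is hardware-side) and reconstructed with Perrin-style
  spherical splines (order m = 4, 7 Legendre terms, ridge 1e-8) on an
  idealized unit-sphere layout of the 16 montage labels. The coordinates
  are the standard idealized 10-10 placements, not digitized positions.
* **Segmentation** yields floor((T − W)/S) + 1 windows; recordings shorter
  than one window give an empty segment set with a warning.

## Synthetic EEG generator

Real recordings for this task are not publicly available, so validation
runs on synthetic EEG built to emulate the relevant structure: per band,
four independent narrowband sources (band-pass-filtered Gaussian noise)
mixed into 16 channels through a per-subject random mixing matrix with
row-normalized loadings; plus per-channel 1/f background noise
(spectral exponent 1, amplitude 5 μV); plus optional blink-like ocular
transients (slow raised-cosine pulses, frontally weighted, 150 μV peak)
and myogenic bursts (>30 Hz noise bursts, temporally weighted, 100 μV
peak) with ground truth returned for scoring removal. Oscillation
amplitudes default to a plausible resting spectrum (Delta 4, Theta 3,
Alpha1 3, Alpha2 2.5, Beta1 2, Beta2 1.5, Gamma 1.5 μV).

The class effect is a multiplicative power ratio in one configured band:
"post" recordings have everything inside the effect band rescaled so the
measured post/pre band-power ratio equals `effect_ratio` (at ratio 1 the
two class generators are identical in distribution). Narrowband noise
rather than sinusoids is used so the effect is a power shift, matching how
band power is analysed in EEG, and not a phase-lockable artifact.

What the generator does **not** emulate: event-related potential
morphology, non-stationarity across a session, volume-conduction head
models, inter-subject spectral shape differences, or electrode drift.
Passing the end-to-end checks therefore demonstrates that the pipeline and
model behave correctly on data with a known band-power effect — not that
the published human-data accuracies are reproduced; those depend on
unavailable recordings.

## Cross-validation and evaluation

`kfold_split()` offers segment-level stratified folds and subject-level
folds. Overlapping windows from one recording share half their samples,
so segment-level splitting leaks recording identity into the test folds
and inflates accuracy; the package's own experiments therefore default to
subject-wise folds, and the segment strategy carries that warning in its
documentation. Metrics are accuracy, precision, recall, F1 (class 1
positive) and rank-based AUC (ties counted half; undefined AUC is reported
as missing, never as 0). The Mann–Whitney U test uses midranks, an exact
enumeration-distribution p-value for tie-free samples with n·m ≤ 400, and
a tie-corrected, continuity-corrected normal approximation otherwise;
p < 0.01 is the significance convention for the behavioral comparisons.

## Prediction uncertainty

The per-sample uncertainty is the normalized predictive entropy
H(p̄)/log K of the mean class probabilities over K = 30 Monte-Carlo
forward passes (fresh ε each pass). This definition is an interpretation —
the quantity is bounded in [0, 1], 0 iff the mean prediction is
degenerate, 1 iff uniform, and invariant to class count; the Monte-Carlo
standard deviation of the class-1 probability is reported alongside as an
alternative. The "acceptable" rate is the fraction of samples with
uncertainty ≤ 0.3, and the occurrence-rate histogram uses width-0.1 bins
by default. K = 30 keeps the entropy estimate's variance small relative to
that bin width.

## Problem sizes used in the packaged experiments

The shipped tests and the acceptance script validate the stack end to end
at sizes chosen to exercise realistic conditions: 40 subjects × (one pre +
one post) recording of 6 s each, giving 200 two-second segments per class
after windowing; a reduced DU-former (16 filters, embed 16, 2 blocks,
strides 10/10) trained with Adam 1e-3, minibatch 16, plateau halving of
the learning rate, patience 4 and at most 20 epochs; subject-wise
cross-validation at 10 folds for the effect and null conditions, 5 folds
for the off-effect band and 3 folds for the ablation comparison (the
acceptance script uses 5/5/3). The effect condition injects a power ratio
of 2.0 in Gamma; the control uses ratio 1.0. With these sizes the
synthetic classes are separable by band power, the null stays at chance,
and an off-effect band (Delta) stays near chance, which is the
band-specificity check.

## Numerical choices and degenerate inputs

* σ positivity: softplus + floor 1e-4 (layer normalization can emit
  negatives).
* Batch statistics need at least two samples; size-1 leftover minibatches
  are skipped by the trainer.
* Softmax and entropy computations subtract row maxima / guard `0·log 0`.
* The adaptive max-pool resolves ties toward the earliest token.
* EDF encoding quantizes to 16-bit integers over a symmetric physical
  range with the reader's gain/offset convention, so round-trip error is
  bounded by half a quantization step; the header timestamp is fixed so
  identical recordings produce identical bytes.
* All randomness fans out from one user seed through a documented
  stage-tag derivation, so every stage is independently reproducible.

## Known limitations

* The synthetic generator's Gaussianity makes ICA formally unidentifiable
  on artifact-free recordings (see the status flag above); real EEG is
  more non-Gaussian and better conditioned for ICA.
* On strongly separable synthetic data the ablation variants can all
  saturate near perfect accuracy, in which case the relative ordering of
  full vs module-excluded variants observed on harder human data need not
  reproduce.
* The baselines are transparent minimal stand-ins, not faithful
  re-implementations of any published comparator configuration.
* Training is CPU-bound base R; it is sized for hundreds of segments, not
  for large-scale studies.
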