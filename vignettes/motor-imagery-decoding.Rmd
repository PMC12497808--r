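---
title: "Decoding motor imagery from EEG: model, training protocol and interpretability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from EEG: model, training protocol and interpretability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieeg)
```

## The problem

Motor imagery (MI) — mentally rehearsing a movement without executing it —
produces a decodable EEG signature: event-related desynchronization (ERD),
a drop in mu-band (~8–12 Hz) power over sensorimotor cortex, with a
class-specific spatial pattern (left-hand imagery attenuates the rhythm
contralaterally, and so on). A brain–computer interface must recover the
imagined class from a short multi-channel epoch, typically the 4 s
following a visual cue (1000 samples at 250 Hz on the canonical 22-channel,
4-class and 3-channel, 2-class competition benchmarks). The difficulty is
that the discriminative structure lives at several temporal scales at once:
cycles of the rhythm itself, the second-scale ERD window, and slower
trial-level dynamics.

`mieeg` implements a compact end-to-end decoder for this problem, together
with the full experimental apparatus around it: segmentation–recombination
data augmentation, a deterministic training protocol, leave-one-subject-out
(LOSO) transfer with graded adaptation, chance-corrected metrics, paired
model-comparison statistics, and a perturbation/Grad-CAM interpretability
suite. Because no deep-learning framework is assumed, every layer — the
convolutions, batch normalisation, multi-head attention, weight-normalised
causal convolutions, and the Adam optimiser with full backpropagation — is
implemented in the package itself (the heavy 1-D convolutions in compiled
code), which makes the parameter accounting and the gradients fully
transparent and testable.

## The network

The model is a composition of five stages; `model_config()` carries every
hyperparameter and `count_parameters()` reproduces the per-block
trainable-parameter tallies exactly.

1. **Convolution block.** A temporal convolution (`F1 = 16` filters, kernel
   32 samples, no bias) acts on each channel, followed by batch norm; a
   depthwise spatial convolution then learns `D = 2` channel combinations
   per temporal filter (kernel `(C, 1)`, no bias), giving `F2 = 32` feature
   maps; batch norm, ELU, average pooling by 8 and dropout complete the
   stage. The even temporal kernel is padded asymmetrically (16 left, 15
   right) so the output keeps exactly `T` samples.
2. **Multi-scale temporal convolutions.** Four parallel biased convolutions
   with kernels 15/31/51/75 (8 filters each, same-length odd padding),
   concatenated back to 32 maps, batch-normalised, ELU-activated, pooled by
   8 again. For `T = 1000` this leaves a sequence of 15 steps of width 32.
3. **Self-attention encoder.** Four identical post-norm transformer layers:
   8-head scaled dot-product attention (head dimension 4, biased Q/K/V/O
   projections), residual + layer norm, then a 32→128→32 GELU feed-forward,
   residual + layer norm. No positional encoding is added — the
   convolutional front end already confers temporal ordering on the
   tokens.
4. **Channel compression + squeeze-and-excitation.** A bias-free 1×1
   convolution compresses 32→16 maps (batch norm, ELU); global average
   pooling, a 16→4 ReLU bottleneck and a 4→16 sigmoid gate (both bias-free)
   rescale each map multiplicatively.
5. **Temporal fusion network.** Two residual blocks of dilated causal
   convolutions (kernel `Kt = 4`; dilations 1 and 2). Block 1 uses a
   depthwise-separable causal pair (depthwise kernel-4 + pointwise 1×1)
   followed by a kernel-4 causal convolution, with batch norm, ELU and
   dropout; its residual is a 1×1 projection of the block input. Block 2
   repeats the pattern at dilation 2 and fuses three paths —
   its own convolutional path, block 1's output, and the *same* projected
   network input (no second projection is allocated) — under a final ELU.
   The pointwise and kernel-4 convolutions carry weight normalisation (one
   gain per output channel); causality is realised as left-only padding of
   `(Kt − 1) · dilation` samples. The receptive field,
   `1 + 2(Kt − 1)(2^L − 1) = 19` steps for `Kt = 4, L = 2`, covers the
   15-step sequence.
6. **Classifier.** The full `32 × 15` feature map is flattened and mapped
   affinely to the K class logits.

For the reference 22-channel, 4-class configuration the stages count
1,312 / 44,128 / 50,816 / 672 / 11,024 / 1,924 trainable parameters —
109,876 in total:

```{r}
count_parameters(model_config())
```

### Design choices where the architecture left room

Several structural details are underdetermined by block diagrams alone; the
package fixes them as follows, choosing in each case the reading that
reconciles the printed per-block parameter tallies:

* **Attention depth and FFN width.** Four encoder layers with a 128-wide
  feed-forward are the unique pair consistent with the 109,876 total, given
  the per-layer attention cost 4·32·33 = 4,224.
* **Weight-norm gains** sit on the pointwise and kernel-4 convolutions of
  the temporal network (not on the depthwise or residual projections); this
  is the unique assignment reproducing the 576/1,088/4,160/544/80/160
  entries. Depthwise convolutions carry a bias (a per-channel gain would
  count identically; the bias reading is used).
* **Bias policy.** Temporal, spatial-depthwise, 1×1-compression and SE
  transforms are bias-free; multi-scale branch convolutions are biased.
* **Classifier input.** All 15 time steps are flattened (480→K); a
  last-step-only head would not reconcile the total.
* **Block-2 fusion** is additive three-way (the only parameter-free
  wiring), and the block-1 projection is reused for the input path.
* **Ordering around pooling.** The multi-scale stage reshapes, pools by 8,
  then applies dropout; the channel/SE stage operates on the pooled
  15-step sequence (the pooling-free ops make the parameter count
  insensitive to this, but shapes are fixed this way throughout).
* **In-path activations** of the temporal network follow the layer listing:
  conv → ELU → batch norm → dropout inside the path, with the block output
  activated after the residual sum.

## Training and evaluation protocol

`train()` runs minibatch Adam (moments 0.9/0.999, no schedule, no early
stopping, no validation split) on the cross-entropy of the logits: batch
size 32, learning rate 5e-4, no weight decay, final-epoch weights kept.
Descriptions of this training recipe occasionally quote 1e-4 instead of
5e-4; the methods-level value 5e-4 is the default here. Inputs are fed
raw (provider-side filtering only, no z-scoring) — an explicit protocol
choice, kept here as the default behaviour with no normalisation option.

Everything is deterministic for a fixed seed: initialisation, shuffling,
dropout masks and augmentation draws all flow from seeded R RNG streams,
and two runs with identical `(seed, data, config)` produce bit-identical
weights (this is a test invariant).

`evaluate()` returns accuracy, the confusion matrix, and Cohen's kappa from
the confusion marginals. `kappa_from_accuracy()` implements the
balanced-chance shortcut `(acc − 1/K)/(1 − 1/K)` that benchmark tables use
when printing a kappa next to a mean accuracy. Note that published
baseline rows reproduced from third-party papers sometimes print kappas
computed from actual confusion matrices instead; those do not — and should
not — agree with the balanced-chance formula applied to the printed mean.

### Augmentation

`segment_recombine()` cuts each 1000-sample training trial into 8
contiguous 125-sample segments and builds new same-class trials by drawing
every segment slot from a uniformly chosen donor trial of that class, all
channels moving together so spatial correlations survive. The
multiplication factor (how many augmented trials per original) is not
pinned down by the protocol description; the package default is `factor =
1` (set doubled), generated once before training rather than re-sampled per
epoch, because a static augmented set keeps the whole run reproducible
under one seed. Donors are drawn with replacement and independently per
segment; duplicates of existing trials are permitted. Test sets are never
augmented — the function signature only accepts a training set, and
train/test provenance ids are checked for disjointness.

### Transfer

`loso_pretrain()` pools the training sessions of all subjects but the
target (verified by provenance ids) and trains 200 epochs from scratch;
`finetune_with_rate()` adapts all layers (none frozen) for 200 epochs on a
single subset of the target's training session — `floor(rate · n)` trials,
drawn once per rate. The draw is stratified by class, a detail the protocol
leaves open, because an unstratified 10% draw of a small session can lose a
class entirely. Augmentation, if used, is applied to the pooled pretraining
set only.

## Statistics

`summarize_accuracies()` (mean, n−1 sd) and `paired_t()` reproduce the
benchmark comparison tables: two-sided paired t-test (via `stats::t.test`),
Cohen's d for paired designs (mean difference / sd of differences) and the
95% CI of the mean difference. The bundled
`mi_benchmark_accuracies()` tables carry the published per-subject
accuracies; because those inputs are rounded to two decimals, recomputed
t/d values are expected to match the published ones to about ±0.005 and CI
bounds to ±0.01. No multiple-testing correction is applied (none was in the
source comparisons).

## Synthetic data: what it emulates and what it does not

`synth_epochs()` generates class-conditional MI-like trials so that every
pipeline is testable without the (non-redistributable) competition
recordings. Each trial is 1/f-shaped background noise (white noise shaped
with power exponent 1, a realistic EEG spectrum) on every channel, plus a
10 Hz random-phase sinusoid on designated "sensorimotor" channels. For a
trial of class k the sinusoid amplitude on that class's channels is
multiplied by `1 − erd_depth` inside the ERD window — amplitude attenuation
of an ongoing rhythm, the defining feature of ERD. Defaults model a
realistic two-class scenario: 100 trials/class, 8 channels, 4-s trials at
250 Hz, rhythm amplitude twice the noise sd, 80% attenuation over 1–3 s
post-cue, one ERD channel per class. The random phase rules out any
template-matching shortcut; band-power analysis (Welch-style periodograms,
`band_power()`) is the oracle used in tests to confirm the generator does
what it claims, and separability grows monotonically with `erd_depth`.

What the generator does **not** emulate: volume conduction and realistic
scalp topography, ocular/muscular artifacts, non-stationarity across a
session, and inter-subject variability beyond what different seeds
produce. Passing the synthetic learnability tests therefore demonstrates
that the architecture, gradients and training loop work — not that the
model attains any particular accuracy on real recordings.

## Interpretability

Four perturbation families (`perturb_time_slices`, `perturb_time_segment`,
`perturb_channels`, `perturb_spatial_region`) zero parts of the raw input;
`output_difference()` scores each as the Euclidean distance between clean
and perturbed **logits**, averaged over trials. Logits rather than softmax
probabilities: near-saturated probabilities would hide sensitivity that the
pre-activation outputs still express. Spatial regions (5 channels × 200
samples) are enumerated channel-major and 1-based, with the last channel
block allowed to be smaller; any published region numbering under a
different ordering must be translated. On models trained on the synthetic
family, the sensitivity profile localises the ERD: the output difference
grows monotonically with the zeroed time fraction, peaks for segments
overlapping the ERD window, and is larger when ERD channels are zeroed than
when noise channels are.

`grad_cam()` explains a class logit at the temporal network's output
feature map. Because the classifier is affine in the flattened map, the
gradient is closed-form (the class row of the classifier weights); the
per-feature weights are its time-average and the temporal relevance is the
signed weighted sum of feature maps (sign separates power increase from
decrease). The per-channel projection — the published procedure projects
onto a scalp map without fully specifying the operator — multiplies the
summed temporal relevance by the normalised absolute depthwise
spatial-filter weights per channel; on trained synthetic models the top
channel coincides with a configured ERD channel.

`export_attention()` returns the `(layers × heads × 15 × 15)`
row-stochastic attention maps averaged over trials.

## Numerical and reproducibility notes

* Batch norm uses momentum 0.1 running statistics (unbiased variance) for
  evaluation mode; evaluation is strictly causal in the temporal network,
  while training-mode batch statistics necessarily couple time steps.
* Dropout (rate 0.3 everywhere, including attention probabilities and
  encoder sublayer outputs) uses inverted scaling and is inactive at
  evaluation.
* Initialisation is Glorot-uniform for weights, zeros for biases, ones for
  norm scales; weight-norm gains start at the weight norms so the initial
  effective weight equals the raw one.
* All arithmetic is double precision; gradients of every one of the 113
  parameter tensors are verified against central finite differences in the
  development suite, and the packaged tests verify parameter-count
  formulae against brute-force enumeration over randomised configurations.
* The container format round-trips at stored precision (R serialisation of
  the `X`/`y`/`fs`/`channel_names`/`class_names` keys).

### Problem sizes used in the packaged checks

The test suite trains the full-length model (8 channels × 1000 samples,
two classes, 100 trials/class, 50 epochs) once and reuses it for the
interpretability oracles; structural and statistical checks are instant.
Unit tests use a reduced geometry (4 channels × 256 samples) whose 1-s
trials carry five rhythm cycles in the ERD window — enough to verify
learning dynamics and protocol mechanics in seconds, though generalisation
at that scale is necessarily weaker than at full trial length. These sizes
are the package's chosen test conditions, small enough to run anywhere yet
large enough that the learnability and localisation oracles are
informative.

## Known limitations

* Only `L = 2` residual blocks are constructible (the multi-level fusion
  wiring is defined for exactly two); the receptive-field formula accepts
  any `L`.
* No GDF reader is bundled; epochs arrive via the array container (an
  adapter around an external EEG-IO reader can produce the same structure).
* Attention-head count and the other architectural defaults are fixed to
  the reference configuration; alternative channel-attention modules (ECA,
  CBAM) are out of scope.
* The CPU implementation favours clarity and exactness over speed: a
  full 1000-epoch training on a real-size dataset is feasible but slow;
  the packaged protocols are demonstrated at reduced epoch counts.
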