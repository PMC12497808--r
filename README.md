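# mieeg — motor-imagery EEG decoding with multi-scale temporal attention

`mieeg` decodes motor-imagery (MI) intentions from epoched multi-channel
EEG. During imagined movement the sensorimotor mu rhythm (~8–12 Hz)
desynchronizes — its power drops — with a class-specific spatial pattern;
a brain–computer interface must read the imagined class from the 4 s of
signal following a cue. The package is aimed at BCI researchers who want a
fully transparent, dependency-light reference implementation of a modern
compact decoder, complete with the experimental protocol around it.

## The model

The decoder composes five stages over an input trial `X ∈ ℝ^{C×T}`
(canonically 22×1000 at 250 Hz):

1. **Spatio-temporal convolution block** — F₁ = 16 temporal filters
   (kernel 32), then a depthwise spatial convolution learning D = 2
   channel projections per filter (F₂ = 32 maps), BN/ELU/avg-pool 8.
2. **Multi-scale temporal convolutions** — four parallel kernels
   (15, 31, 51, 75) of 8 filters each, concatenated, pooled by 8 again to a
   15-step sequence of width 32.
3. **Self-attention encoder** — 4 post-norm transformer layers, 8 heads of
   dimension 4: `Attention(Q,K,V) = softmax(QKᵀ/√d_k)V`, each followed by a
   32→128→32 GELU feed-forward, residuals and layer norm.
4. **Channel compression + squeeze-and-excitation** — 1×1 conv 32→16, then
   a global-pool → 16→4→16 bottleneck gate `W = σ(W₂ δ(W₁ z))`.
5. **Dilated causal temporal fusion network** — two weight-normalised
   depthwise-separable causal residual blocks (kernel K_t = 4, dilations
   1, 2) with multi-level residual fusion; receptive field
   `1 + 2(K_t−1)(2^L−1) = 19 > 15`. A flattened affine head yields the K
   class logits.

Every layer — convolutions, batch norm, attention, weight norm, Adam, and
full backpropagation — is implemented in the package (compiled kernels for
the convolutions), so the trainable-parameter accounting is exact: 1,312 +
44,128 + 50,816 + 672 + 11,024 + 1,924 = **109,876** parameters for the
reference configuration.

Around the network: within-class segmentation–recombination augmentation
(8 × 125-sample segments), a deterministic training protocol (Adam, batch
32, lr 5e-4, seed-reproducible), leave-one-subject-out transfer with graded
adaptation rates, accuracy/kappa evaluation, paired t / Cohen's d model
comparison, a four-family perturbation sensitivity suite and Grad-CAM
relevance maps, plus a synthetic generator of class-conditional
event-related-desynchronization EEG that makes the whole pipeline testable
without external recordings.

## Worked example

```r
library(mieeg)

# architecture and exact parameter accounting
count_parameters(model_config(C = 22, T_samples = 1000, n_classes = 4))
#> conv_block        1,312
#> ms_conv          44,128
#> sa_encoder       50,816
#> channel_se          672
#> tdscfn           11,024
#> classifier        1,924
#> total           109,876
receptive_field(4, 2)
#> [1] 19

# synthetic two-class ERD data at full trial length (8 channels, 4 s)
train_set <- synth_epochs(synth_config(seed = 1))
test_set  <- synth_epochs(synth_config(seed = 2))
train_set
#> <eeg_epochs> 200 trials x 8 channels x 1000 samples @ 250 Hz, 2 classes
#>   per-class counts: 0=100, 1=100

# augmentation doubles the set by within-class segment recombination
aug <- segment_recombine(train_set, augmentation_config(n_segments = 8,
                                                        segment_len = 125))
aug
#> <eeg_epochs> 400 trials x 8 channels x 1000 samples @ 250 Hz, 2 classes
#>   per-class counts: 0=200, 1=200

# train briefly and evaluate on held-out trials
model <- build_model(model_config(C = 8, T_samples = 1000, n_classes = 2),
                     seed = 0)
model <- train(model, aug, train_config(epochs = 10, seed = 0))
ev <- evaluate(model, test_set)
round(c(accuracy = ev$accuracy, kappa = ev$kappa), 4)
#> accuracy    kappa
#>        1        1
```

Ten epochs suffice on this clean synthetic family: the generator plants an
80% mu-power attenuation on one channel per class, so a working
architecture + training loop should separate the classes essentially
perfectly — the interesting checks are the interpretability oracles
(`perturbation_sweep()`, `grad_cam()`), which verify the trained model
localises the ERD window and channels it was trained on.

```r
# chance-corrected kappa implied by published mean accuracies
kappa_from_accuracy(0.8492, K = 4)   #> 0.7989333
kappa_from_accuracy(0.8841, K = 2)   #> 0.7682

# paired comparison on bundled published per-subject accuracies
tab <- mi_benchmark_accuracies("bcic2a")
paired_t(tab$accuracy[tab$method == "Proposed"],
         tab$accuracy[tab$method == "EEGNet-8.2"])
#> paired t-test: mean diff 12.46, t(8) = 6.273, p = 0.0002, d = 2.091,
#>   95% CI [7.881, 17.044]
```

A command-line front end (`inst/cli/mieeg.R`) exposes the same pipeline as
`synth` / `augment` / `build` / `train` / `stats` / `perturb` subcommands.

See `vignettes/motor-imagery-decoding.Rmd` for the full account of the
model, the protocol defaults, the synthetic generator's scope, and the
design decisions taken where the architecture description left room.

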