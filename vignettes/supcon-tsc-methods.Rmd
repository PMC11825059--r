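---
title: "Two-level supervised contrastive learning for multivariate time series: methods and design notes"
author: "SupConTSC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level supervised contrastive learning for multivariate time series: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multivariate time series classification (MTSC) assigns one discrete label
to an m-channel series of length l. In clinical settings such as
cardiopulmonary exercise testing (CPET), labelled recordings are scarce:
a cross-entropy-trained deep network easily overfits, and the learned
decision boundaries have poor margins. `SupConTSC` addresses this with a
two-stage procedure:

1. **Representation learning.** A Siamese 1D residual convolutional
   encoder is pre-trained with a *supervised contrastive* (SupCon)
   objective that pulls same-class embeddings together and pushes
   different-class embeddings apart on the unit hypersphere.
2. **Classification.** The projection head is discarded, the encoder is
   frozen, and a small MLP classifier is trained on the pooled encoder
   features with cross-entropy.

The contrastive stage is applied at two levels. The *instance level*
contrasts each case against the other cases of its mini-batch. The
*cluster level* contrasts each case against per-class cluster centers
accumulated across recent batches in a FIFO memory bank; it targets the
situation where classes are internally multimodal and mutually similar,
which a purely instance-wise objective handles poorly.

## The objective

Each case `x` is jittered twice: a strong draw `x_s = x + N(0, σ_s²)`
feeds the source branch and a weak draw `x_t = x + N(0, σ_w²)` feeds the
target branch. Both branches share one encoder `E` and projection head
`proj`; embeddings are L2-normalised,
`z = normalize(proj(E(x)))`.

For a batch of N pairs, with anchor `z_k^s` and comparison set
`A(k) = {1, …, N}` over target embeddings, the instance-level loss per
anchor is

```
L_k^ins = -(1/|P(k)|) * Σ_{p ∈ P(k)} log[ exp(z_k^s · z_p^t / τ)
                                          / Σ_{a ∈ A(k)} exp(z_k^s · z_a^t / τ) ]
```

where `P(k)` are the targets sharing the anchor's label — always
including k itself, so the loss is defined even for a batch-singleton
class — and τ is the temperature.

After each batch, the per-class arithmetic means of the (detached)
target embeddings are appended to the memory bank. The cluster-level
loss has the same form with the bank contents as the comparison set;
anchors whose class is absent from the bank contribute zero and are
counted in a `skipped` diagnostic. The total objective is the sum over
anchors of `L_k^ins + α · L_k^clus`, where the warm-up gate α is 0 for
`epoch ≤ N_w` and 1 afterwards: early in training the bank holds
embeddings of an essentially random encoder, and contrasting against
them would inject noise.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tau` | 0.1 | softmax temperature of both contrastive losses |
| `sigmaStrong` / `sigmaWeak` | 0.5 / 0.05 | jitter sd (z-normalised units) of the source/target views |
| `batchSize` | 32 | contrastive batch N (last incomplete batch dropped in stage 1) |
| `epochs` / `warmupEpochs` | 30 / `ceil(0.2·epochs)` | stage-1 length and warm-up N_w |
| `bankCapacity` | 16 | batch snapshots retained in the memory bank |
| `blockFilters` | 64/128/128 | encoder filters (kernels 8/5/3) |
| `projDim` | 64 | contrastive embedding dimension D |
| `lr`, `lrClassifier` | 1e-3 | Adam learning rates per stage |

The jitter variances and τ were chosen once as round defaults an order
of magnitude apart ("high-variance" vs "low-variance" jitter); all are
exposed in `trainConfig()`. The encoder is the canonical time-series
ResNet configuration (three residual blocks of three
convolution–batchnorm–ReLU layers, stride 1, same padding, global
average pooling), so the final feature maps align 1:1 with input time
steps — a property the attribution module relies on.

## Design choices where the design was open

- **Classifier input.** The stage-2 classifier consumes the pooled
  encoder feature h, not the contrastive embedding z: the projection
  head is discarded before classification, and h is the "universal
  representation" the method preserves.
- **Warm-up boundary.** α switches at `epoch > N_w` (the gate is off
  *through* epoch N_w). An off-by-one alternative (off strictly below
  N_w) exists; the package follows the piece-wise definition and the
  schedule is unit-tested at both boundary epochs.
- **Shared weights, detached history.** Source and target branches
  share one weight set; gradients flow through both views. Bank entries
  are stored detached: no gradient propagates into activations of past
  batches. There is no momentum/EMA target network.
- **Cluster centers are plain means.** Centers are not re-normalised by
  default, so their dot products carry each cluster's concentration
  (tight clusters produce larger-magnitude similarities). A
  `renormalizeCenters` flag restores unit-norm centers, which changes
  the effective temperature of the cluster term.
- **Eviction policy.** The bank evicts whole batch snapshots
  oldest-first (a ring over batches of size `bankCapacity`), matching
  its `N_buffer × N_l × D` geometry. Duplicate labels across batches
  are kept — the bank is explicitly a history, not a dictionary.
- **Reduction.** The combined loss is a *sum* over anchors; a `"mean"`
  reduction is available for batch-size robustness, with the learning
  rate absorbing the scale otherwise.
- **Missing data.** Ragged or missing positions carry mask 0 and, after
  `znormalize()`, the fill value 0 — the post-normalisation channel
  mean, inert under convolution. The mask is carried through the
  pipeline and exposed, and jitter never perturbs masked positions, but
  the default encoder does not consume the mask (no masked architecture
  is part of the method); `maskAsChannels` in `encoderConfig()` lets a
  user concatenate it as extra input channels.
- **Zero-based labels.** Class ids are `0..c-1` in sorted lexicographic
  order of the label strings, fixed across train/test splits, so a test
  split can never silently remap classes.

## Numerical choices

Both losses subtract the per-anchor maximum logit before
exponentiation (log-sum-exp stabilisation). The z-normalisation sd has
a floor of 1e-8 so constant channels are safe. Softmax probabilities
are clamped at 1e-300 inside the cross-entropy. Ensemble prediction
averages softmax outputs (not logits) and breaks argmax ties toward
the lowest class id. Batch normalisation uses batch statistics during
training (momentum 0.1 running updates) and running statistics at
inference; stage-2 feature extraction therefore happens in inference
mode, making the frozen features deterministic.

The network engine is written against BLAS: activations flow as
`channels × (l·N)` matrices and each convolution is one matrix product
over a compiled im2col unrolling. All backward passes are explicit and
are verified against central finite differences in the test suite.

## The synthetic generator

`makeMTSC()` emulates exactly the statistical structure the method
assumes: class-specific smooth motifs (sinusoid mixtures) per channel,
optional sub-cluster *modes* per class (intra-class multimodality),
an `interSim` factor that blends all motifs toward their common mean
(inter-class similarity), i.i.d. Gaussian within-class noise
(`intraVar`), and optional ragged truncation to exercise
padding/masking. `makeWindowedMTSC()` builds a two-class set whose
classes differ only inside a known time window, giving a ground-truth
target for attribution localisation. `makeEmbeddingFixture()` produces
clustered unit-norm embedding pairs for loss-level oracles.

What the generator deliberately does **not** emulate: real CPET
waveform physiology (exercise bouts, recovery kinetics, inter-variable
cross-correlation), non-stationary sampling rates, label noise, and
class imbalance. Passing the packaged studies therefore demonstrates
that the implementation optimises its objective and recovers planted
structure — not that the method attains any particular accuracy on
real archives.

## Study scales

The packaged end-to-end studies run on one CPU at desk scale, chosen
once. The *recovery* study uses 3 classes × 50 cases of 3 × 64 series
with an 80/20 stratified holdout (stage-1 epochs 8, warm-up 2, stage-2
epochs 25). The *ablation* study deliberately uses a limited-label
regime — 3 classes × 20 cases with two modes per class and strong
motif overlap — because that is the setting contrastive pre-training
targets: with abundant data both arms sit at an accuracy ceiling and
the comparison measures seed noise. Both arms receive equal epoch
budgets (stage-1 30 + stage-2 30; the cross-entropy-only baseline
trains encoder and classifier jointly for the summed 60 epochs), and
the stage-2 readout uses learning rate 1e-2 so the frozen-feature
classifier converges within that budget. The *attribution* study uses
60 cases of 2 × 48 (stage-1 epochs 8, stage-2 10). Five seeds per
study; medians are reported.

## Known limitations

- Batch normalisation couples cases within a batch, so stage-1
  training is deterministic only for a fixed batch size and seed.
- The contrastive losses degrade for very small batches (N = 1 is a
  defined but uninformative case); the trainer drops the last
  incomplete stage-1 batch for this reason.
- The memory bank stores centers produced by *past* encoder states;
  with very long warm-ups or tiny datasets the bank may be stale
  relative to the current encoder. The warm-up gate mitigates but does
  not eliminate this.
- Attribution is temporal only (no per-channel maps), mirroring the
  method's scope.
- The `.ts` reader targets the sktime dialect plus plain ARFF and a
  long CSV format; exotic timestamped dialects are out of scope.
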