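# SupConTSC

Supervised contrastive representation learning for multivariate time
series classification (MTSC), for settings — typical of clinical series
such as cardiopulmonary exercise testing — where labelled recordings are
too scarce for plain cross-entropy training to learn discriminative
features.

## Method

A case is an m-channel series of length l with one discrete label.
Training is two-stage:

**Stage 1 — representation.** Each case `x` is jittered twice,
`x_s = x + N(0, σ_s²)` (strong, source branch) and
`x_t = x + N(0, σ_w²)` (weak, target branch). A shared 1D-ResNet
encoder `E` (3 residual blocks, filters 64/128/128, kernels 8/5/3,
global average pooling) and projection head give unit-norm embeddings
`z = normalize(proj(E(x)))`. The loss combines two temperature-scaled
supervised contrastive terms, summed over anchors k:

    L = Σ_k [ L_k^ins + α · L_k^clus ]

    L_k^ins  = -(1/|P(k)|) Σ_{p∈P(k)} log  exp(z_k^s·z_p^t/τ) / Σ_{a∈A(k)} exp(z_k^s·z_a^t/τ)

with `A(k)` all target embeddings of the batch and `P(k)` those sharing
the anchor's label (anchor's own target view included). `L_k^clus` has
the same form against per-class cluster centers (plain means of the
target embeddings) accumulated across recent batches in a FIFO memory
bank of `N_buffer` batch snapshots; the gate α is 0 during the first
`N_w` warm-up epochs and 1 afterwards.

**Stage 2 — classification.** The projection head is discarded and a
two-layer softmax MLP is trained with cross-entropy on the frozen
pooled features `h = GAP(E(x))`. An ablation switch
(`withSupCon = FALSE`) instead trains encoder + classifier jointly with
cross-entropy only.

The package also provides: a sktime/UEA `.ts` reader (plus ARFF and a
long CSV format) with padding/masking of ragged series and masked
z-normalisation; a synthetic generator of class-structured multichannel
signals; Grad-CAM time-step attribution
(`w_k = mean_t ∂y_c/∂A_k(t)`, `relevance(t) = ReLU(Σ_k w_k A_k(t))`)
at the final convolutional layer; stratified k-fold ensembling by
softmax averaging; and classifier-comparison statistics (win/tie
counts, tie-corrected Friedman test, pairwise Wilcoxon signed-rank with
Holm correction and clique grouping).

## Worked example

```r
library(SupConTSC)

ds <- makeMTSC(syntheticSpec(nClasses = 3, nPerClass = 50, m = 3, l = 64,
                             intraVar = 0.3, interSim = 0.2, seed = 101))
folds <- stratifiedFolds(classLabels(ds), 5, seed = 1)
tr <- which(folds != 1); ho <- which(folds == 1)
sub <- function(i) mtscDataset(seriesValues(ds)[i, , ], seriesMask(ds)[i, , ],
                               classLabels(ds)[i], classNames(ds))
zn  <- znormalize(sub(tr))
hold <- znormalize(sub(ho), stats = zn$stats)$dataset

cfg <- trainConfig(batchSize = 32, epochs = 8, warmupEpochs = 2,
                   epochsClassifier = 25, seed = 1)
fit <- fitSupConTSC(zn$dataset, cfg)
head(fit$trace, 3)
#>   epoch alpha instanceLoss clusterLoss skippedAnchors
#> 1     1     0     92.69157     0.00000              0
#> 2     2     0     76.17214     0.00000              0
#> 3     3     1     76.29223    91.82116              0

pred <- predictDataset(fit$net, seriesValues(hold))
accuracyScore(classLabels(hold), pred$labels)
#> [1] 1
```

The trace shows the per-epoch mean of the summed instance-level loss,
the cluster-level term engaging after the two warm-up epochs (alpha
switching 0 to 1), and no skipped anchors (every anchor found a
same-class center in the bank). Held-out accuracy 1.0 on this easy
three-class dataset says the planted structure was recovered.

Attribution on a trained model:

```r
map <- gradcamAttribute(fit$net, seriesValues(hold)[1, , ], classId = 0L)
relevance(map)   # length-64 non-negative per-time-step relevance
```

A thin CLI over these functions ships in `inst/cli/supcon-tsc.R`
(subcommands `synth`, `pretrain`, `train-classifier`, `ablation`,
`predict`, `explain`, `compare`).

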