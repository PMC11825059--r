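# Independent brute-force oracles and small fixtures shared across tests.

# Naive double-loop instance-level supervised contrastive loss.
naiveInstanceLoss <- function(zs, zt, labels, tau) {
  N <- nrow(zs)
  per <- numeric(N)
  for (k in seq_len(N)) {
    P <- which(labels == labels[k])          # includes k itself
    denom <- 0
    for (a in seq_len(N)) denom <- denom + exp(sum(zs[k, ] * zt[a, ]) / tau)
    acc <- 0
    for (p in P) {
      acc <- acc + log(exp(sum(zs[k, ] * zt[p, ]) / tau) / denom)
    }
    per[k] <- -acc / length(P)
  }
  list(perAnchor = per, total = sum(per))
}

# Naive double-loop cluster-level loss against explicit bank contents.
naiveClusterLoss <- function(zs, labels, bankLabels, bankCenters, tau) {
  N <- nrow(zs)
  per <- numeric(N)
  skipped <- 0L
  for (k in seq_len(N)) {
    P <- which(bankLabels == labels[k])
    if (length(P) == 0L) { skipped <- skipped + 1L; next }
    denom <- 0
    for (a in seq_along(bankLabels)) {
      denom <- denom + exp(sum(zs[k, ] * bankCenters[a, ]) / tau)
    }
    acc <- 0
    for (p in P) {
      acc <- acc + log(exp(sum(zs[k, ] * bankCenters[p, ]) / tau) / denom)
    }
    per[k] <- -acc / length(P)
  }
  list(perAnchor = per, total = sum(per), skipped = skipped)
}

# Random unit-norm embedding batch for oracle-equivalence sweeps.
randomBatch <- function(N, D, nClasses, seed) {
  set.seed(seed)
  mk <- function() {
    z <- matrix(rnorm(N * D), N, D)
    z / sqrt(rowSums(z^2))
  }
  list(zs = mk(), zt = mk(),
       labels = sample(0:(nClasses - 1L), N, replace = TRUE))
}

# Reference deque simulation of the FIFO bank semantics.
refBankSim <- function(updates, capacity) {
  entries <- list()                          # each: label, batch
  for (u in updates) {
    for (lb in u$labels) {
      entries[[length(entries) + 1L]] <- list(label = lb, batch = u$batch)
    }
    batches <- unique(vapply(entries, function(e) e$batch, numeric(1)))
    while (length(batches) > capacity) {
      drop <- batches[1L]
      entries <- Filter(function(e) e$batch != drop, entries)
      batches <- batches[-1L]
    }
  }
  list(labels = vapply(entries, function(e) e$label, numeric(1)),
       batches = vapply(entries, function(e) e$batch, numeric(1)))
}

# Tiny network configuration used wherever the architecture itself is
# not the thing under test.
tinyEncoderConfig <- function(m = 2L, c = 2L) {
  encoderConfig(m, c, blockFilters = c(4L, 6L, 6L),
                kernelSizes = c(5L, 3L, 3L), projDim = 4L,
                projHidden = 8L, clsHidden = 8L)
}

tinyTrainConfig <- function(seed = 1L, ...) {
  args <- list(batchSize = 8L, epochs = 2L, warmupEpochs = 1L,
               epochsClassifier = 3L, blockFilters = c(4L, 6L, 6L),
               kernelSizes = c(5L, 3L, 3L), projDim = 4L, projHidden = 8L,
               clsHidden = 8L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(trainConfig, args)
}

tinyDataset <- function(seed = 5L, n = 12L) {
  makeMTSC(syntheticSpec(nClasses = 2L, nPerClass = n, m = 2L, l = 16L,
                         intraVar = 0.2, seed = seed))
}

writeTsFixture <- function(lines) {
  path <- tempfile(fileext = ".ts")
  writeLines(lines, path)
  path
}

# Stratified 80/20 train/holdout split with training-statistics
# normalisation (fold 1 of 5 is the holdout).
splitTrainHold <- function(ds, seed) {
  folds <- stratifiedFolds(classLabels(ds), 5L, seed)
  tr <- which(folds != 1L); ho <- which(folds == 1L)
  dsTr <- mtscDataset(seriesValues(ds)[tr, , , drop = FALSE],
                      seriesMask(ds)[tr, , , drop = FALSE],
                      classLabels(ds)[tr], classNames(ds))
  znTr <- znormalize(dsTr)
  dsHo <- mtscDataset(seriesValues(ds)[ho, , , drop = FALSE],
                      seriesMask(ds)[ho, , , drop = FALSE],
                      classLabels(ds)[ho], classNames(ds))
  znHo <- znormalize(dsHo, stats = znTr$stats)
  list(train = znTr$dataset, hold = znHo$dataset, stats = znTr$stats)
}
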