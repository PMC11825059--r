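#' Two-stage training configuration
#'
#' Stage 1 pre-trains the encoder + projection head with the two-level
#' supervised contrastive objective; stage 2 trains the classifier on the
#' frozen pooled features with cross-entropy. With `withSupCon = FALSE`
#' the contrastive stage is skipped entirely and encoder + classifier are
#' trained jointly from scratch with cross-entropy only (the ablation
#' baseline); that arm runs for `epochs + epochsClassifier` epochs so
#' both arms see a comparable number of optimisation passes.
#'
#' @param batchSize contrastive mini-batch size N (>= 2; the last
#'   incomplete batch is dropped in stage 1 and kept in stage 2).
#' @param epochs stage-1 epochs N_e.
#' @param warmupEpochs N_w, epochs before the cluster-level term engages;
#'   default `ceiling(0.2 * epochs)`, must be < `epochs`.
#' @param epochsClassifier stage-2 epochs.
#' @param tau contrastive temperature (default 0.1).
#' @param augment an [augmentSpec()].
#' @param bankCapacity memory-bank capacity in batch snapshots (default 16).
#' @param lr,lrClassifier Adam learning rates for the two stages.
#' @param kFolds folds for [kfoldEnsemble()] (default 5).
#' @param seed master seed; every random choice (weights, shuffling,
#'   augmentation, folds) derives from it.
#' @param withSupCon `TRUE` for the full two-stage method, `FALSE` for
#'   the cross-entropy-only baseline.
#' @param blockFilters,kernelSizes,projDim,projHidden,clsHidden encoder
#'   architecture, see [encoderConfig()].
#' @param reduction,renormalizeCenters see [lossConfig()].
#' @return a validated `TrainConfig` list.
#' @export
trainConfig <- function(batchSize = 32L, epochs = 30L, warmupEpochs = NULL,
                        epochsClassifier = 30L, tau = 0.1,
                        augment = augmentSpec(), bankCapacity = 16L,
                        lr = 1e-3, lrClassifier = 1e-3, kFolds = 5L,
                        seed = 1L, withSupCon = TRUE,
                        blockFilters = c(64L, 128L, 128L),
                        kernelSizes = c(8L, 5L, 3L), projDim = 64L,
                        projHidden = 128L, clsHidden = 128L,
                        reduction = "sum", renormalizeCenters = FALSE) {
  if (is.null(warmupEpochs)) warmupEpochs <- ceiling(0.2 * epochs)
  stopifnot(batchSize >= 2L, epochs >= 1L, warmupEpochs >= 0L,
            warmupEpochs <= epochs, epochsClassifier >= 1L, tau > 0,
            inherits(augment, "AugmentationSpec"), bankCapacity >= 1L,
            lr > 0, lrClassifier > 0, kFolds >= 2L)
  structure(list(batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 warmupEpochs = as.integer(warmupEpochs),
                 epochsClassifier = as.integer(epochsClassifier),
                 tau = tau, augment = augment,
                 bankCapacity = as.integer(bankCapacity), lr = lr,
                 lrClassifier = lrClassifier, kFolds = as.integer(kFolds),
                 seed = as.integer(seed), withSupCon = isTRUE(withSupCon),
                 blockFilters = as.integer(blockFilters),
                 kernelSizes = as.integer(kernelSizes),
                 projDim = as.integer(projDim),
                 projHidden = as.integer(projHidden),
                 clsHidden = as.integer(clsHidden), reduction = reduction,
                 renormalizeCenters = renormalizeCenters),
            class = "TrainConfig")
}

.batchArray <- function(ds, idx) {
  seriesValues(ds)[idx, , , drop = FALSE]
}

.ceLoss <- function(logits, labels0) {
  # logits: c x N, labels0 zero-based; mean cross-entropy + gradient
  N <- ncol(logits)
  p <- .softmaxCols(logits)
  ii <- cbind(labels0 + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[ii], 1e-300)))
  dlogits <- p
  dlogits[ii] <- dlogits[ii] - 1
  list(loss = loss, dlogits = dlogits / N)
}

#' Stage 1: contrastive representation pre-training
#'
#' Runs the two-level supervised contrastive algorithm: per batch, the
#' strong and weak jittered views are encoded and projected by the shared
#' network, per-class cluster centers of the (detached) target embeddings
#' are pushed into the FIFO memory bank, and the summed instance-level
#' plus warm-up-gated cluster-level loss is minimised with Adam.
#' Deterministic under `cfg$seed`.
#'
#' @param ds a finalised [MTSCDataset-class] (see [znormalize()]) with at
#'   least 2 classes.
#' @param cfg a [trainConfig()].
#' @return a `FitResult` list: `net` (the trained handle), `trace`
#'   (per-epoch data.frame: epoch, alpha, instanceLoss, clusterLoss,
#'   skippedAnchors), `foldId`.
#' @export
pretrainRepresentation <- function(ds, cfg) {
  stopifnot(is(ds, "MTSCDataset"), inherits(cfg, "TrainConfig"))
  n <- nCases(ds)
  if (cfg$batchSize > n) {
    stop("batchSize (", cfg$batchSize, ") exceeds the number of cases (",
         n, ")")
  }
  c <- length(classNames(ds))
  if (c < 2L) stop("contrastive pre-training needs >= 2 classes")
  ecfg <- encoderConfig(nChannels(ds), c, cfg$blockFilters,
                        cfg$kernelSizes, cfg$projDim, cfg$projHidden,
                        cfg$clsHidden)
  net <- buildNetwork(ecfg, cfg$seed)
  bank <- clusterMemoryBank(cfg$projDim, cfg$bankCapacity)
  labels <- classLabels(ds)
  vals <- seriesValues(ds)
  msk <- seriesMask(ds)
  trace <- data.frame(epoch = integer(), alpha = numeric(),
                      instanceLoss = numeric(), clusterLoss = numeric(),
                      skippedAnchors = integer())
  globalBatch <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    alpha <- alphaSchedule(epoch, cfg$warmupEpochs)
    set.seed(deriveSeed(cfg$seed, 1000L + epoch))
    perm <- sample.int(n)
    nBatches <- n %/% cfg$batchSize           # drop last incomplete batch
    insSum <- 0; clusSum <- 0; skipSum <- 0L
    for (bi in seq_len(nBatches)) {
      globalBatch <- globalBatch + 1L
      idx <- perm[((bi - 1L) * cfg$batchSize + 1L):(bi * cfg$batchSize)]
      x <- vals[idx, , , drop = FALSE]
      mk <- msk[idx, , , drop = FALSE]
      views <- makeViews(x, cfg$augment, mk,
                         rngSeed = deriveSeed(cfg$seed,
                                              100000L + globalBatch))
      es <- .toEngine(views$strong)
      et <- .toEngine(views$weak)
      fs <- .encoderFwd(net, es$x, es$l, es$N, TRUE)
      ps <- .mlpFwd(net, fs$h, "proj")
      ns <- .l2normFwd(ps$y)
      ft <- .encoderFwd(net, et$x, et$l, et$N, TRUE)
      pt <- .mlpFwd(net, ft$h, "proj")
      nt <- .l2normFwd(pt$y)
      batch <- embeddingBatch(t(ns$z), t(nt$z), labels[idx])
      bank <- bankUpdate(bank, clusterCenters(batch@zTarget, batch@labels),
                         globalBatch)
      ins <- instanceSupConLoss(batch, cfg$tau, gradient = TRUE)
      if (alpha > 0) {
        clus <- clusterSupConLoss(batch@zSource, batch@labels, bank,
                                  cfg$tau, gradient = TRUE,
                                  renormalizeCenters = cfg$renormalizeCenters)
      } else {
        clus <- list(total = 0, skipped = cfg$batchSize,
                     gradSource = batch@zSource * 0)
      }
      scale <- if (cfg$reduction == "mean") 1 / cfg$batchSize else 1
      dzS <- scale * t(ins$gradSource + alpha * clus$gradSource)  # D x N
      dzT <- scale * t(ins$gradTarget)
      grads <- list()
      dvS <- .l2normBwd(list(z = ns$z, nrm = ns$nrm), dzS)
      mbS <- .mlpBwd(net, ps, dvS, "proj")
      grads <- .sumGrads(grads, mbS$grads)
      ebS <- .encoderBwd(net, fs, mbS$dh)
      grads <- .sumGrads(grads, ebS$grads)
      dvT <- .l2normBwd(list(z = nt$z, nrm = nt$nrm), dzT)
      mbT <- .mlpBwd(net, pt, dvT, "proj")
      grads <- .sumGrads(grads, mbT$grads)
      ebT <- .encoderBwd(net, ft, mbT$dh)
      grads <- .sumGrads(grads, ebT$grads)
      .adamStep(net, grads, cfg$lr)
      insSum <- insSum + scale * ins$total
      clusSum <- clusSum + alpha * scale * clus$total
      skipSum <- skipSum + if (alpha > 0) clus$skipped else 0L
    }
    trace <- rbind(trace, data.frame(
      epoch = epoch, alpha = alpha, instanceLoss = insSum / nBatches,
      clusterLoss = clusSum / nBatches, skippedAnchors = skipSum))
  }
  structure(list(net = net, trace = trace, stage2Trace = NULL,
                 foldId = NA_integer_), class = "FitResult")
}

#' Stage 2: classifier training
#'
#' With `cfg$withSupCon = TRUE`, trains the classifier head on the frozen
#' pooled features of `net` (encoder weights are bit-identical before and
#' after; the projection head is discarded). With `withSupCon = FALSE`,
#' ignores `net` and trains a fresh encoder + classifier jointly with
#' cross-entropy only, touching neither projection head nor memory bank.
#'
#' @param ds a finalised [MTSCDataset-class].
#' @param net a pre-trained `SupConNet` (or `NULL` when
#'   `cfg$withSupCon = FALSE`).
#' @param cfg a [trainConfig()].
#' @return a `FitResult` list: `net`, `trace` (stage-1 trace when
#'   present), `stage2Trace` (per-epoch cross-entropy).
#' @export
trainClassifier <- function(ds, net, cfg) {
  stopifnot(is(ds, "MTSCDataset"), inherits(cfg, "TrainConfig"))
  labels <- classLabels(ds)
  n <- nCases(ds)
  if (cfg$withSupCon) {
    stopifnot(is(net, "SupConNet"))
    if (length(classNames(ds)) > net$cfg$nClasses) {
      stop("dataset has ", length(classNames(ds)),
           " classes but the checkpoint was built for ", net$cfg$nClasses)
    }
    if (nChannels(ds) != net$cfg$inChannels) {
      stop("dataset channel count does not match the checkpoint")
    }
    H <- t(encodeFeatures(net, seriesValues(ds)))   # Dh x n, frozen
    net$adam <- .adamInit(net$params)               # fresh optimiser state
    ceTrace <- numeric(cfg$epochsClassifier)
    for (epoch in seq_len(cfg$epochsClassifier)) {
      set.seed(deriveSeed(cfg$seed, 5000L + epoch))
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batchSize)      # keep incomplete batch
      lossSum <- 0
      for (st in starts) {
        idx <- perm[st:min(st + cfg$batchSize - 1L, n)]
        cl <- .mlpFwd(net, H[, idx, drop = FALSE], "cls")
        ce <- .ceLoss(cl$y, labels[idx])
        mb <- .mlpBwd(net, cl, ce$dlogits, "cls")
        .adamStep(net, mb$grads, cfg$lrClassifier)
        lossSum <- lossSum + ce$loss
      }
      ceTrace[epoch] <- lossSum / length(starts)
    }
    return(structure(list(net = net, trace = NULL,
                          stage2Trace = data.frame(
                            epoch = seq_len(cfg$epochsClassifier),
                            crossEntropy = ceTrace),
                          foldId = NA_integer_), class = "FitResult"))
  }
  # ablation baseline: joint encoder + classifier, cross-entropy only
  ecfg <- encoderConfig(nChannels(ds), length(classNames(ds)),
                        cfg$blockFilters, cfg$kernelSizes, cfg$projDim,
                        cfg$projHidden, cfg$clsHidden)
  net <- buildNetwork(ecfg, cfg$seed)
  nEpochs <- cfg$epochs + cfg$epochsClassifier
  vals <- seriesValues(ds)
  ceTrace <- numeric(nEpochs)
  for (epoch in seq_len(nEpochs)) {
    set.seed(deriveSeed(cfg$seed, 5000L + epoch))
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batchSize)
    lossSum <- 0
    for (st in starts) {
      idx <- perm[st:min(st + cfg$batchSize - 1L, n)]
      if (length(idx) < 2L) next                    # batch-norm needs >= 2
      eb <- .toEngine(vals[idx, , , drop = FALSE])
      fwd <- .encoderFwd(net, eb$x, eb$l, eb$N, TRUE)
      cl <- .mlpFwd(net, fwd$h, "cls")
      ce <- .ceLoss(cl$y, labels[idx])
      mb <- .mlpBwd(net, cl, ce$dlogits, "cls")
      ebk <- .encoderBwd(net, fwd, mb$dh)
      .adamStep(net, .sumGrads(mb$grads, ebk$grads), cfg$lrClassifier)
      lossSum <- lossSum + ce$loss
    }
    ceTrace[epoch] <- lossSum / length(starts)
  }
  structure(list(net = net, trace = NULL,
                 stage2Trace = data.frame(epoch = seq_len(nEpochs),
                                          crossEntropy = ceTrace),
                 foldId = NA_integer_), class = "FitResult")
}

#' Full two-stage fit
#'
#' Convenience wrapper: stage-1 pre-training (when `cfg$withSupCon`)
#' followed by stage-2 classifier training on the same data.
#'
#' @inheritParams pretrainRepresentation
#' @return a `FitResult` with both traces.
#' @export
fitSupConTSC <- function(ds, cfg) {
  if (cfg$withSupCon) {
    fit1 <- pretrainRepresentation(ds, cfg)
    fit2 <- trainClassifier(ds, fit1$net, cfg)
    structure(list(net = fit2$net, trace = fit1$trace,
                   stage2Trace = fit2$stage2Trace, foldId = NA_integer_),
              class = "FitResult")
  } else {
    trainClassifier(ds, NULL, cfg)
  }
}

#' Stratified fold assignment
#'
#' @param labels integer labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids 1..k, stratified by class.
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  folds <- integer(length(labels))
  for (lb in sort(unique(labels))) {
    idx <- which(labels == lb)
    if (length(idx) < k) {
      stop("class '", lb, "' has ", length(idx),
           " members, fewer than kFolds = ", k)
    }
    set.seed(deriveSeed(seed, 7000L + as.integer(lb)))
    folds[idx] <- (sample(seq_along(idx)) - 1L) %% k + 1L
  }
  folds
}

#' k-fold cross-validated ensemble
#'
#' Trains one full two-stage model per stratified fold (the fold's
#' complement is the training set) and records each fold's validation
#' accuracy.
#'
#' @inheritParams pretrainRepresentation
#' @return list of `FitResult`s of length `cfg$kFolds`, each with
#'   `foldId`, `valIndices` and `valAccuracy`.
#' @export
kfoldEnsemble <- function(ds, cfg) {
  stopifnot(is(ds, "MTSCDataset"), inherits(cfg, "TrainConfig"))
  folds <- stratifiedFolds(classLabels(ds), cfg$kFolds, cfg$seed)
  lapply(seq_len(cfg$kFolds), function(f) {
    trIdx <- which(folds != f)
    vaIdx <- which(folds == f)
    dsTr <- mtscDataset(seriesValues(ds)[trIdx, , , drop = FALSE],
                        seriesMask(ds)[trIdx, , , drop = FALSE],
                        classLabels(ds)[trIdx], classNames(ds),
                        channelNames(ds))
    cfgF <- cfg
    cfgF$seed <- deriveSeed(cfg$seed, 8000L + f)
    fit <- fitSupConTSC(dsTr, cfgF)
    pred <- predictDataset(fit$net, seriesValues(ds)[vaIdx, , ,
                                                     drop = FALSE])
    fit$foldId <- f
    fit$valIndices <- vaIdx
    fit$valAccuracy <- accuracyScore(classLabels(ds)[vaIdx], pred$labels)
    fit
  })
}

#' Predict class ids and probabilities for a batch
#'
#' @param net a trained `SupConNet`.
#' @param x numeric batch `N x m x l`.
#' @return list with `labels` (zero-based ids; ties broken toward the
#'   lowest id) and `probabilities` (`N x c`).
#' @export
predictDataset <- function(net, x) {
  probs <- classify(net, x)
  list(labels = max.col(probs, ties.method = "first") - 1L,
       probabilities = probs)
}

#' Ensemble prediction by softmax averaging
#'
#' Probabilities are averaged arithmetically across models (softmax
#' outputs, not logits), then the argmax is taken with ties broken toward
#' the lowest class id.
#'
#' @param models list of `FitResult`s (or `SupConNet`s) sharing one class
#'   mapping.
#' @param x numeric batch `N x m x l`.
#' @return list with `labels` and `probabilities` as [predictDataset()].
#' @export
predictEnsemble <- function(models, x) {
  nets <- lapply(models, function(mdl) {
    if (inherits(mdl, "FitResult")) mdl$net else mdl
  })
  cs <- vapply(nets, function(nt) nt$cfg$nClasses, integer(1))
  if (length(unique(cs)) != 1L) {
    stop("models disagree on the class mapping (", paste(unique(cs),
         collapse = ", "), " classes)")
  }
  probs <- Reduce(`+`, lapply(nets, function(nt) classify(nt, x))) /
    length(nets)
  list(labels = max.col(probs, ties.method = "first") - 1L,
       probabilities = probs)
}
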