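test_that("pretraining is deterministic and traces follow the schedule", {
  ds <- znormalize(tinyDataset())$dataset
  cfg <- tinyTrainConfig(seed = 9, epochs = 3L, warmupEpochs = 1L)
  f1 <- pretrainRepresentation(ds, cfg)
  f2 <- pretrainRepresentation(ds, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$net$params, f2$net$params)
  expect_equal(nrow(f1$trace), 3L)
  expect_equal(f1$trace$alpha, c(0, 1, 1))
  # cluster term is identically zero through the warm-up
  expect_equal(f1$trace$clusterLoss[1], 0)
  expect_gt(f1$trace$clusterLoss[2], 0)
})

test_that("a full warm-up silences the cluster term in every epoch", {
  ds <- znormalize(tinyDataset())$dataset
  cfg <- tinyTrainConfig(seed = 2, epochs = 2L, warmupEpochs = 2L)
  fit <- pretrainRepresentation(ds, cfg)
  expect_equal(fit$trace$alpha, c(0, 0))
  expect_equal(fit$trace$clusterLoss, c(0, 0))
})

test_that("batch size larger than the dataset is rejected", {
  ds <- znormalize(tinyDataset(n = 3L))$dataset
  cfg <- tinyTrainConfig(batchSize = 64L)
  expect_error(pretrainRepresentation(ds, cfg), "exceeds")
})

test_that("stage 2 freezes the encoder bit-for-bit", {
  ds <- znormalize(tinyDataset())$dataset
  cfg <- tinyTrainConfig(seed = 4)
  fit1 <- pretrainRepresentation(ds, cfg)
  frozen <- fit1$net$params[grep("^(enc|proj)\\.", names(fit1$net$params))]
  fit2 <- trainClassifier(ds, fit1$net, cfg)
  after <- fit2$net$params[grep("^(enc|proj)\\.", names(fit2$net$params))]
  expect_identical(after, frozen)
  # but the classifier moved
  expect_false(identical(fit2$net$params[["cls.fc2.W"]],
                         buildNetwork(fit1$net$cfg, cfg$seed)$params[["cls.fc2.W"]]))
})

test_that("separable frozen features are fit to perfect accuracy", {
  ds <- znormalize(makeMTSC(syntheticSpec(nClasses = 2, nPerClass = 12,
                                          m = 2, l = 16, intraVar = 0.05,
                                          seed = 8)))$dataset
  cfg <- tinyTrainConfig(seed = 8, epochs = 8L, warmupEpochs = 2L,
                         epochsClassifier = 50L, lrClassifier = 1e-2)
  pre <- pretrainRepresentation(ds, cfg)
  # oracle: the frozen pooled features are linearly separable
  H <- encodeFeatures(pre$net, seriesValues(ds))
  lgf <- suppressWarnings(
    glm(classLabels(ds) ~ H, family = binomial,
        control = list(maxit = 100)))
  expect_equal(mean((fitted(lgf) > 0.5) == classLabels(ds)), 1.0)
  # the stage-2 classifier reaches the same training accuracy
  fit <- trainClassifier(ds, pre$net, cfg)
  pred <- predictDataset(fit$net, seriesValues(ds))
  expect_equal(accuracyScore(classLabels(ds), pred$labels), 1.0)
})

test_that("the cross-entropy baseline never touches head or bank", {
  ds <- znormalize(tinyDataset())$dataset
  cfg <- tinyTrainConfig(seed = 3, withSupCon = FALSE, epochs = 2L,
                         epochsClassifier = 2L)
  fit <- fitSupConTSC(ds, cfg)
  expect_null(fit$trace)                       # no contrastive stage ran
  init <- buildNetwork(fit$net$cfg, cfg$seed)
  projNames <- grep("^proj\\.", names(init$params), value = TRUE)
  expect_identical(fit$net$params[projNames], init$params[projNames])
  encNames <- grep("^enc\\.", names(init$params), value = TRUE)
  expect_false(identical(fit$net$params[encNames], init$params[encNames]))
})

test_that("stratified folds partition the data with balanced classes", {
  labels <- rep(0:2, each = 50)
  folds <- stratifiedFolds(labels, 5, seed = 6)
  expect_equal(sort(unique(folds)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(folds == f), 30)
    expect_equal(as.integer(table(labels[folds == f])), c(10L, 10L, 10L))
  }
  expect_identical(folds, stratifiedFolds(labels, 5, seed = 6))
  expect_error(stratifiedFolds(c(0, 0, 1), 2, 1), "class '1'")
})

test_that("ensemble prediction averages softmax outputs with the tie rule", {
  ds <- znormalize(tinyDataset())$dataset
  x <- seriesValues(ds)[1:4, , , drop = FALSE]
  nets <- lapply(c(11, 22), function(s) {
    buildNetwork(tinyEncoderConfig(m = 2L, c = 2L), s)
  })
  ens <- predictEnsemble(nets, x)
  manual <- (classify(nets[[1]], x) + classify(nets[[2]], x)) / 2
  expect_equal(ens$probabilities, manual, tolerance = 1e-14)
  expect_equal(ens$labels, max.col(manual, ties.method = "first") - 1L)

  # identical models reduce to the single-model prediction
  same <- predictEnsemble(list(nets[[1]], nets[[1]]), x)
  expect_equal(same$probabilities, classify(nets[[1]], x), tolerance = 1e-14)

  # exact tie resolves to the lowest class id
  tieNet <- buildNetwork(tinyEncoderConfig(m = 2L, c = 2L), 1)
  tieNet$params[["cls.fc2.W"]][] <- 0
  tieNet$params[["cls.fc2.b"]][] <- 0
  expect_true(all(predictEnsemble(list(tieNet), x)$labels == 0L))
})

test_that("k-fold ensembling trains one model per disjoint fold", {
  ds <- znormalize(makeMTSC(syntheticSpec(nClasses = 2, nPerClass = 10,
                                          m = 2, l = 16, intraVar = 0.1,
                                          seed = 12)))$dataset
  cfg <- tinyTrainConfig(seed = 12, kFolds = 2L, epochs = 1L,
                         warmupEpochs = 0L, epochsClassifier = 2L)
  fits <- kfoldEnsemble(ds, cfg)
  expect_length(fits, 2L)
  idx <- sort(unlist(lapply(fits, function(f) f$valIndices)))
  expect_equal(idx, seq_len(nCases(ds)))
  expect_equal(vapply(fits, function(f) f$foldId, integer(1)), 1:2)
  expect_true(all(vapply(fits, function(f) f$valAccuracy, numeric(1)) >= 0))
})

test_that("the instance-level loss declines over pre-training", {
  ds <- znormalize(makeMTSC(syntheticSpec(nClasses = 2, nPerClass = 16,
                                          m = 2, l = 16, intraVar = 0.2,
                                          seed = 5)))$dataset
  cfg <- tinyTrainConfig(seed = 7, batchSize = 8L, epochs = 6L,
                         warmupEpochs = 2L)
  fit <- pretrainRepresentation(ds, cfg)
  expect_lt(fit$trace$instanceLoss[6], fit$trace$instanceLoss[1])
})
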