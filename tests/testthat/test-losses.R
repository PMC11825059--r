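test_that("instance loss reproduces its closed-form values", {
  # singleton batch: numerator equals denominator
  b1 <- embeddingBatch(matrix(c(1, 0), 1), matrix(c(1, 0), 1), 0L)
  expect_equal(instanceSupConLoss(b1, tau = 0.3)$total, 0, tolerance = 1e-12)

  # two identical same-label pairs: each softmax term is 1/2
  v <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
  b2 <- embeddingBatch(v, v, c(0L, 0L))
  for (tau in c(0.1, 1, 5)) {
    expect_equal(instanceSupConLoss(b2, tau)$perAnchor, rep(log(2), 2),
                 tolerance = 1e-9)
  }

  # two-point different-label case: softplus of the similarity gap
  zs <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  zt <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  b3 <- embeddingBatch(zs, zt, c(0L, 1L))
  out <- instanceSupConLoss(b3, tau = 1)
  expect_equal(out$perAnchor[1], log(1 + exp(-1)), tolerance = 1e-9)
  expect_equal(out$perAnchor[1], 0.313262, tolerance = 1e-6)
})

test_that("vectorized losses match the naive double-loop oracle", {
  for (i in 1:100) {
    set.seed(1000 + i)
    N <- sample(2:16, 1); D <- sample(2:8, 1); c <- sample(2:4, 1)
    tau <- runif(1, 0.05, 1)
    rb <- randomBatch(N, D, c, seed = 2000 + i)
    batch <- embeddingBatch(rb$zs, rb$zt, rb$labels)
    fast <- instanceSupConLoss(batch, tau)
    ref <- naiveInstanceLoss(rb$zs, rb$zt, rb$labels, tau)
    expect_lt(max(abs(fast$perAnchor - ref$perAnchor)), 1e-6)

    B <- sample(1:6, 1)
    bl <- sample(0:(c - 1), B, replace = TRUE)
    bc <- matrix(rnorm(B * D), B, D)
    bank <- clusterMemoryBank(D, 4L)
    bank <- bankUpdate(bank, list(labels = bl, centers = bc), 1L)
    fastC <- clusterSupConLoss(rb$zs, rb$labels, bank, tau)
    refC <- naiveClusterLoss(rb$zs, rb$labels, bl, bc, tau)
    expect_lt(max(abs(fastC$perAnchor - refC$perAnchor)), 1e-6)
    expect_equal(fastC$skipped, refC$skipped)
  }
})

test_that("total loss is invariant to permuting the batch", {
  rb <- randomBatch(10, 5, 3, seed = 77)
  batch <- embeddingBatch(rb$zs, rb$zt, rb$labels)
  ref <- instanceSupConLoss(batch, 0.2)$total
  for (i in 1:5) {
    set.seed(i)
    p <- sample(10)
    bp <- embeddingBatch(rb$zs[p, ], rb$zt[p, ], rb$labels[p])
    expect_equal(instanceSupConLoss(bp, 0.2)$total, ref, tolerance = 1e-10)
  }
})

test_that("loss decreases in anchor-positive similarity, increases in
           anchor-negative similarity", {
  lossAt <- function(ePos, eNeg) {
    zs <- rbind(c(1, 0, 0), c(0, 1, 0))
    zt <- rbind(c(cos(ePos), 0, sin(ePos)),
                c(sin(eNeg), cos(eNeg), 0))
    instanceSupConLoss(embeddingBatch(zs, zt, c(0L, 1L)), 0.5)$perAnchor[1]
  }
  # widening the anchor-positive angle raises anchor 1's loss
  expect_lt(lossAt(0.1, 0), lossAt(0.4, 0))
  expect_lt(lossAt(0.4, 0), lossAt(1.2, 0))
  # raising anchor-negative similarity (zt2 toward zs1) raises it too
  expect_lt(lossAt(0.3, 0), lossAt(0.3, 0.8))

  # perfect-separation comparison: orthogonalising one positive hurts
  zsA <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ztAligned <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ztSwapped <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  lab <- c(0L, 0L, 1L)
  lA <- instanceSupConLoss(embeddingBatch(zsA, ztAligned, lab), 0.1)$total
  lS <- instanceSupConLoss(embeddingBatch(zsA, ztSwapped, lab), 0.1)$total
  expect_lt(lA, lS)
})

test_that("analytic loss gradients match finite differences", {
  rb <- randomBatch(6, 4, 2, seed = 31)
  batch <- embeddingBatch(rb$zs, rb$zt, rb$labels)
  out <- instanceSupConLoss(batch, 0.3, gradient = TRUE)
  h <- 1e-6
  for (trial in 1:4) {
    set.seed(trial)
    i <- sample(6, 1); j <- sample(4, 1)
    for (side in c("s", "t")) {
      zp <- rb$zs; ztp <- rb$zt
      if (side == "s") zp[i, j] <- zp[i, j] + h else ztp[i, j] <- ztp[i, j] + h
      # bypass the unit-norm validity check: call the naive oracle
      fp <- naiveInstanceLoss(zp, ztp, rb$labels, 0.3)$total
      if (side == "s") zp[i, j] <- zp[i, j] - 2 * h else
        ztp[i, j] <- ztp[i, j] - 2 * h
      fm <- naiveInstanceLoss(zp, ztp, rb$labels, 0.3)$total
      num <- (fp - fm) / (2 * h)
      an <- if (side == "s") out$gradSource[i, j] else out$gradTarget[i, j]
      expect_lt(abs(num - an) / max(1e-6, abs(num)), 1e-4)
    }
  }

  bank <- clusterMemoryBank(4, 4L)
  bank <- bankUpdate(bank, list(labels = c(0L, 1L),
                                centers = matrix(rnorm(8), 2, 4)), 1L)
  outC <- clusterSupConLoss(rb$zs, rb$labels, bank, 0.3, gradient = TRUE)
  bv <- bankView(bank)
  for (trial in 1:3) {
    set.seed(100 + trial)
    i <- sample(6, 1); j <- sample(4, 1)
    zp <- rb$zs; zp[i, j] <- zp[i, j] + h
    fp <- naiveClusterLoss(zp, rb$labels, bv$labels, bv$centers, 0.3)$total
    zp[i, j] <- zp[i, j] - 2 * h
    fm <- naiveClusterLoss(zp, rb$labels, bv$labels, bv$centers, 0.3)$total
    num <- (fp - fm) / (2 * h)
    expect_lt(abs(num - outC$gradSource[i, j]) / max(1e-6, abs(num)), 1e-4)
  }
})

test_that("cluster centers are exact per-label means", {
  # one instance per label: centers equal the embeddings
  z <- matrix(rnorm(6), 3, 2)
  cc <- clusterCenters(z, c(2L, 0L, 1L))
  expect_equal(cc$labels, c(0L, 1L, 2L))
  expect_equal(cc$centers, z[c(2, 3, 1), ], tolerance = 1e-15)

  cc2 <- clusterCenters(rbind(c(1, 0), c(0, 1)), c(0L, 0L))
  expect_equal(cc2$centers, matrix(c(0.5, 0.5), 1), tolerance = 1e-15)

  set.seed(4)
  z8 <- matrix(rnorm(8 * 3), 8, 3)
  z8 <- z8 / sqrt(rowSums(z8^2))
  lab <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L)
  cc3 <- clusterCenters(z8, lab)
  for (i in seq_along(cc3$labels)) {
    expect_lt(max(abs(cc3$centers[i, ] -
                      colMeans(z8[lab == cc3$labels[i], , drop = FALSE]))),
              1e-12)
  }
})

test_that("cluster loss handles degenerate banks per contract", {
  bank1 <- bankUpdate(clusterMemoryBank(2, 4L),
                      list(labels = 0L, centers = matrix(c(0.2, 0.4), 1)),
                      1L)
  out <- clusterSupConLoss(matrix(c(1, 0), 1), 0L, bank1, 0.7)
  expect_equal(out$total, 0, tolerance = 1e-12)   # single-entry softmax

  bank2 <- bankUpdate(clusterMemoryBank(2, 4L),
                      list(labels = c(0L, 1L),
                           centers = rbind(c(1, 0), c(0, 1))), 1L)
  out2 <- clusterSupConLoss(matrix(c(1, 0), 1), 0L, bank2, 1)
  expect_equal(out2$total, log(1 + exp(-1)), tolerance = 1e-9)

  empty <- clusterMemoryBank(2, 4L)
  out3 <- clusterSupConLoss(matrix(rnorm(6), 3), c(0L, 1L, 0L), empty, 0.5)
  expect_equal(out3$total, 0)
  expect_equal(out3$skipped, 3L)
})

test_that("the warm-up gate follows the epoch threshold exactly", {
  for (Nw in c(0L, 1L, 5L)) {
    for (epoch in 1:10) {
      expect_equal(alphaSchedule(epoch, Nw), as.numeric(epoch > Nw))
    }
  }
  expect_equal(alphaSchedule(5, 5), 0)
  expect_equal(alphaSchedule(6, 5), 1)
})

test_that("the combined objective composes its two terms", {
  rb <- randomBatch(8, 4, 2, seed = 55)
  batch <- embeddingBatch(rb$zs, rb$zt, rb$labels)
  bank <- bankUpdate(clusterMemoryBank(4, 4L),
                     clusterCenters(rb$zt, rb$labels), 1L)
  ins <- instanceSupConLoss(batch, 0.2)$total
  clus <- clusterSupConLoss(rb$zs, rb$labels, bank, 0.2)$total

  warm <- combinedLoss(batch, bank, 0.2, epoch = 1, warmupEpochs = 3)
  expect_equal(warm$total, ins, tolerance = 1e-12)
  expect_equal(warm$alpha, 0)

  post <- combinedLoss(batch, bank, 0.2, epoch = 4, warmupEpochs = 3)
  expect_equal(post$total, ins + clus, tolerance = 1e-12)

  emptyB <- clusterMemoryBank(4, 4L)
  postE <- combinedLoss(batch, emptyB, 0.2, epoch = 4, warmupEpochs = 3)
  expect_equal(postE$total, ins, tolerance = 1e-12)
})
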