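#' Encoder / head / classifier configuration
#'
#' The encoder is the canonical time-series ResNet: three residual blocks
#' of three conv+batchnorm+ReLU layers (kernel sizes 8/5/3, stride 1,
#' same padding, so temporal length is preserved), a 1x1-conv shortcut
#' where the channel count changes, and global average pooling over time
#' giving the pooled feature h of dimension `blockFilters[3]`. The
#' projection head (linear-ReLU-linear, then L2 normalisation) produces
#' the contrastive embedding z; the classifier (linear-ReLU-linear with
#' softmax) consumes h, never z.
#'
#' @param inChannels number of input channels m.
#' @param nClasses number of classes c.
#' @param blockFilters integer vector of 3 filter counts
#'   (default `c(64, 128, 128)`).
#' @param kernelSizes integer vector of 3 kernel sizes (default `c(8, 5, 3)`).
#' @param projDim contrastive embedding dimension D (default 64).
#' @param projHidden projection-head hidden width (default 128).
#' @param clsHidden classifier hidden width (default 128).
#' @param maskAsChannels if `TRUE`, callers concatenate the observation
#'   mask as m extra input channels (the config then doubles
#'   `inChannels`); default `FALSE`.
#' @return a validated `EncoderConfig` list; `featureDim` is the pooled
#'   feature dimension D_h.
#' @export
encoderConfig <- function(inChannels, nClasses,
                          blockFilters = c(64L, 128L, 128L),
                          kernelSizes = c(8L, 5L, 3L),
                          projDim = 64L, projHidden = 128L,
                          clsHidden = 128L, maskAsChannels = FALSE) {
  stopifnot(length(blockFilters) == 3L, length(kernelSizes) == 3L,
            inChannels >= 1L, nClasses >= 2L, all(blockFilters >= 1L),
            all(kernelSizes >= 1L), projDim >= 2L)
  if (maskAsChannels) inChannels <- 2L * inChannels
  structure(list(inChannels = as.integer(inChannels),
                 nClasses = as.integer(nClasses),
                 blockFilters = as.integer(blockFilters),
                 kernelSizes = as.integer(kernelSizes),
                 featureDim = as.integer(blockFilters[3L]),
                 projDim = as.integer(projDim),
                 projHidden = as.integer(projHidden),
                 clsHidden = as.integer(clsHidden),
                 maskAsChannels = maskAsChannels),
            class = "EncoderConfig")
}

#' Build the Siamese network
#'
#' One weight set serves both augmented views (shared encoder). Weights
#' are initialised deterministically from `seed`.
#'
#' @param cfg an [encoderConfig()].
#' @param seed integer seed for weight initialisation.
#' @return a `SupConNet` handle (an environment holding parameters,
#'   batch-norm running statistics and optimiser state).
#' @export
buildNetwork <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "EncoderConfig"))
  set.seed(deriveSeed(seed, 1L))
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$params <- .initParams(cfg)
  net$bn <- .initBn(cfg)
  net$adam <- .adamInit(net$params)
  net$normStats <- NULL
  class(net) <- "SupConNet"
  net
}

#' @export
print.SupConNet <- function(x, ...) {
  cfg <- x$cfg
  nPar <- sum(vapply(x$params, length, numeric(1)))
  cat("SupConNet:", cfg$inChannels, "channels ->", cfg$featureDim,
      "pooled features ->", cfg$projDim, "contrastive dims;",
      cfg$nClasses, "classes;", nPar, "parameters\n")
  invisible(x)
}

#' Encode and project a batch to unit-norm embeddings
#'
#' `z = normalize(proj(E(x)))`: encoder, projection head, then row-wise
#' L2 normalisation.
#'
#' @param net a [buildNetwork()] handle.
#' @param x numeric batch `N x m x l` (or a single `m x l` case).
#' @param train if `TRUE`, batch-norm uses batch statistics and updates
#'   running statistics; default `FALSE` (inference).
#' @return numeric matrix `N x projDim` with unit-norm rows.
#' @export
encodeProject <- function(net, x, train = FALSE) {
  eb <- .toEngine(x)
  if (eb$m != net$cfg$inChannels) {
    stop("input has ", eb$m, " channels but the network expects ",
         net$cfg$inChannels)
  }
  fwd <- .encoderFwd(net, eb$x, eb$l, eb$N, train)
  pj <- .mlpFwd(net, fwd$h, "proj")
  t(.l2normFwd(pj$y)$z)
}

#' Pooled encoder features h = GAP(E(x))
#'
#' @inheritParams encodeProject
#' @return numeric matrix `N x featureDim`.
#' @export
encodeFeatures <- function(net, x, train = FALSE) {
  eb <- .toEngine(x)
  fwd <- .encoderFwd(net, eb$x, eb$l, eb$N, train)
  t(fwd$h)
}

#' Class probabilities from the classifier head
#'
#' The classifier consumes the pooled encoder features h (the projection
#' head plays no role at inference). Rows are simplex vectors.
#'
#' @inheritParams encodeProject
#' @return numeric matrix `N x nClasses` of softmax probabilities.
#' @export
classify <- function(net, x, train = FALSE) {
  eb <- .toEngine(x)
  fwd <- .encoderFwd(net, eb$x, eb$l, eb$N, train)
  cl <- .mlpFwd(net, fwd$h, "cls")
  t(.softmaxCols(cl$y))
}

#' Save / load a network checkpoint
#'
#' Single-file archive holding weights, configuration, batch-norm running
#' statistics and (optionally) the training-split normalisation
#' statistics, under a versioned schema key. The cluster memory bank is
#' deliberately not part of a checkpoint.
#'
#' @param net a `SupConNet`.
#' @param path file path.
#' @return `path` (save) or the restored `SupConNet` (load).
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(list(schema = "SupConTSC/checkpoint/1", cfg = net$cfg,
               params = net$params, bn = net$bn,
               normStats = net$normStats), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "SupConTSC/checkpoint/1")) {
    stop(path, ": not a SupConTSC checkpoint")
  }
  net <- new.env(parent = emptyenv())
  net$cfg <- x$cfg
  net$params <- x$params
  net$bn <- x$bn
  net$adam <- .adamInit(net$params)
  net$normStats <- x$normStats
  class(net) <- "SupConNet"
  net
}
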