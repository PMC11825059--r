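#' @import methods
NULL

#' MTSCDataset: a labelled multivariate time series collection
#'
#' Container for n cases of m-channel series of common (padded) length l,
#' together with a binary observation mask and integer class labels.
#' Padded or missing positions carry mask 0; after finalisation (see
#' [znormalize()]) they hold the sentinel fill value 0, never `NA`/`NaN`.
#'
#' @slot values numeric array `n x m x l` (cases x channels x time).
#' @slot mask numeric array of the same shape; entries in `{0, 1}`
#'   (1 = observed, 0 = padded/missing).
#' @slot labels integer vector of length n with zero-based class ids
#'   `0..c-1` (the convention of the UEA archive tooling).
#' @slot classNames character vector of length c; `classNames[id + 1]` is
#'   the original label string of class `id`.
#' @slot channelNames character vector of length m.
#'
#' @seealso [mtscDataset()], [readTsFile()], [makeMTSC()]
#' @export
setClass("MTSCDataset",
  representation(
    values = "array",
    mask = "array",
    labels = "integer",
    classNames = "character",
    channelNames = "character"
  )
)

setValidity("MTSCDataset", function(object) {
  v <- object@values
  msk <- object@mask
  msgs <- character()
  if (length(dim(v)) != 3L) {
    msgs <- c(msgs, "'values' must be a 3-d array (cases x channels x time)")
  }
  if (!identical(dim(v), dim(msk))) {
    msgs <- c(msgs, "'values' and 'mask' must have identical shape")
  }
  if (!all(msk %in% c(0, 1))) {
    msgs <- c(msgs, "'mask' entries must be 0 or 1")
  }
  if (length(dim(v)) == 3L) {
    if (length(object@labels) != dim(v)[1L]) {
      msgs <- c(msgs, "'labels' length must equal the number of cases")
    }
    if (length(object@channelNames) != dim(v)[2L]) {
      msgs <- c(msgs, "'channelNames' length must equal the number of channels")
    }
    if (identical(dim(v), dim(msk)) && any(!is.finite(v[msk == 1]))) {
      msgs <- c(msgs, "observed positions (mask = 1) must hold finite values")
    }
  }
  if (length(object@labels) > 0L) {
    if (anyNA(object@labels) || min(object@labels) < 0L ||
        max(object@labels) >= length(object@classNames)) {
      msgs <- c(msgs, "'labels' must lie in 0..(length(classNames) - 1)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an MTSCDataset
#'
#' @param values numeric array `n x m x l`.
#' @param mask numeric array of the same shape with entries in `{0, 1}`;
#'   defaults to all-observed.
#' @param labels integer vector of zero-based class ids of length n.
#' @param classNames character vector of class label strings; defaults to
#'   `as.character(0:(c-1))` inferred from `labels`.
#' @param channelNames character vector of channel names; defaults to
#'   `"ch1".."chm"`.
#' @return An [MTSCDataset-class] object.
#' @examples
#' ds <- mtscDataset(array(rnorm(2 * 3 * 4), c(2, 3, 4)), labels = c(0L, 1L))
#' nCases(ds)
#' @export
mtscDataset <- function(values, mask = NULL, labels,
                        classNames = NULL, channelNames = NULL) {
  values <- unname(values)
  if (is.null(mask)) mask <- array(1, dim(values))
  labels <- as.integer(labels)
  if (is.null(classNames)) {
    classNames <- as.character(seq_len(max(labels) + 1L) - 1L)
  }
  if (is.null(channelNames)) {
    channelNames <- paste0("ch", seq_len(dim(values)[2L]))
  }
  new("MTSCDataset", values = values, mask = unname(mask), labels = labels,
      classNames = classNames, channelNames = channelNames)
}

#' EmbeddingBatch: paired source/target contrastive embeddings
#'
#' Projected, L2-normalised embeddings of one mini-batch. Row i of
#' `zSource` and `zTarget` derive from the same underlying case, seen
#' through the strong and weak augmentation respectively.
#'
#' @slot zSource numeric matrix `N x D`, unit-norm rows (strong view).
#' @slot zTarget numeric matrix `N x D`, unit-norm rows (weak view).
#' @slot labels integer vector of length N (zero-based class ids).
#' @seealso [embeddingBatch()], [makeEmbeddingFixture()]
#' @export
setClass("EmbeddingBatch",
  representation(zSource = "matrix", zTarget = "matrix", labels = "integer")
)

setValidity("EmbeddingBatch", function(object) {
  msgs <- character()
  if (!identical(dim(object@zSource), dim(object@zTarget))) {
    msgs <- c(msgs, "'zSource' and 'zTarget' must have identical shape")
  }
  if (nrow(object@zSource) != length(object@labels)) {
    msgs <- c(msgs, "'labels' length must equal the number of rows")
  }
  norms <- c(sqrt(rowSums(object@zSource^2)), sqrt(rowSums(object@zTarget^2)))
  if (length(norms) && any(abs(norms - 1) > 1e-6)) {
    msgs <- c(msgs, "all embedding rows must have L2 norm 1 (tol 1e-6)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EmbeddingBatch
#'
#' @param zSource,zTarget numeric `N x D` matrices with unit-norm rows.
#' @param labels integer vector of length N.
#' @return An [EmbeddingBatch-class] object.
#' @export
embeddingBatch <- function(zSource, zTarget, labels) {
  new("EmbeddingBatch", zSource = unname(as.matrix(zSource)),
      zTarget = unname(as.matrix(zTarget)), labels = as.integer(labels))
}

#' ClusterMemoryBank: FIFO store of per-class cluster centers
#'
#' Holds the per-class mean target embeddings of the most recent
#' `capacityBatches` batch snapshots. Eviction is strictly
#' oldest-batch-first; the bank never exceeds
#' `capacityBatches x nLabels` entries.
#'
#' @slot dim integer, embedding dimension D.
#' @slot capacityBatches integer, number of batch snapshots retained.
#' @slot labels integer vector, one label per stored center, insertion order.
#' @slot centers numeric matrix, one row per stored center.
#' @slot batchIndex integer vector, the batch index each center came from.
#' @seealso [clusterMemoryBank()], [bankUpdate()], [bankView()]
#' @export
setClass("ClusterMemoryBank",
  representation(
    dim = "integer",
    capacityBatches = "integer",
    labels = "integer",
    centers = "matrix",
    batchIndex = "integer"
  )
)

setValidity("ClusterMemoryBank", function(object) {
  msgs <- character()
  if (object@dim < 1L) msgs <- c(msgs, "'dim' must be >= 1")
  if (object@capacityBatches < 1L) {
    msgs <- c(msgs, "'capacityBatches' must be >= 1")
  }
  n <- length(object@labels)
  if (nrow(object@centers) != n || length(object@batchIndex) != n) {
    msgs <- c(msgs, "'labels', 'centers' rows and 'batchIndex' must agree")
  }
  if (n > 0L && ncol(object@centers) != object@dim) {
    msgs <- c(msgs, "center dimension must equal 'dim'")
  }
  if (is.unsorted(object@batchIndex)) {
    msgs <- c(msgs, "'batchIndex' must be non-decreasing (insertion order)")
  }
  if (length(unique(object@batchIndex)) > object@capacityBatches) {
    msgs <- c(msgs, "more distinct batches stored than 'capacityBatches'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an empty cluster memory bank
#'
#' @param dim embedding dimension D of the centers to be stored.
#' @param capacityBatches number of batch snapshots retained (default 16).
#' @return An empty [ClusterMemoryBank-class].
#' @export
clusterMemoryBank <- function(dim, capacityBatches = 16L) {
  new("ClusterMemoryBank", dim = as.integer(dim),
      capacityBatches = as.integer(capacityBatches),
      labels = integer(0), centers = matrix(0, 0L, as.integer(dim)),
      batchIndex = integer(0))
}

#' AttributionMap: per-time-step Grad-CAM relevance
#'
#' Non-negative relevance of each time step of one case for one class,
#' computed from class-logit gradients at the final convolutional layer.
#'
#' @slot relevance numeric vector of length l, all entries `>= 0`.
#' @slot classId integer, the attributed (zero-based) class id.
#' @slot caseId integer, index of the attributed case (or `NA`).
#' @seealso [gradcamAttribute()]
#' @export
setClass("AttributionMap",
  representation(relevance = "numeric", classId = "integer",
                 caseId = "integer")
)

setValidity("AttributionMap", function(object) {
  if (any(object@relevance < 0)) {
    "'relevance' must be non-negative"
  } else TRUE
})

# ---- accessors ----

#' @describeIn MTSCDataset-class number of cases n.
#' @param x,object an object of the documented class.
#' @export
nCases <- function(x) dim(x@values)[1L]

#' @describeIn MTSCDataset-class number of channels m.
#' @export
nChannels <- function(x) dim(x@values)[2L]

#' @describeIn MTSCDataset-class padded series length l.
#' @export
seriesLength <- function(x) dim(x@values)[3L]

#' @describeIn MTSCDataset-class the `n x m x l` value array.
#' @export
seriesValues <- function(x) x@values

#' @describeIn MTSCDataset-class the `n x m x l` observation mask.
#' @export
seriesMask <- function(x) x@mask

#' @describeIn MTSCDataset-class zero-based integer class labels.
#' @export
classLabels <- function(x) x@labels

#' @describeIn MTSCDataset-class class label strings, id order.
#' @export
classNames <- function(x) x@classNames

#' @describeIn MTSCDataset-class channel names.
#' @export
channelNames <- function(x) x@channelNames

#' @describeIn AttributionMap-class the non-negative relevance vector.
#' @export
relevance <- function(x) x@relevance

setMethod("show", "MTSCDataset", function(object) {
  d <- dim(object@values)
  cat("MTSCDataset:", d[1L], "cases x", d[2L], "channels x", d[3L],
      "time steps\n")
  cat("  classes (", length(object@classNames), "): ",
      paste(object@classNames, collapse = ", "), "\n", sep = "")
  obs <- sum(object@mask)
  cat(sprintf("  observed entries: %d of %d (%.1f%%)\n",
              as.integer(obs), length(object@mask),
              100 * obs / length(object@mask)))
})

setMethod("show", "EmbeddingBatch", function(object) {
  cat("EmbeddingBatch:", nrow(object@zSource), "pairs, dim",
      ncol(object@zSource), "\n")
})

setMethod("show", "ClusterMemoryBank", function(object) {
  cat("ClusterMemoryBank:", length(object@labels), "centers (capacity",
      object@capacityBatches, "batches x classes), dim", object@dim, "\n")
})

setMethod("show", "AttributionMap", function(object) {
  cat("AttributionMap: class", object@classId, "case", object@caseId,
      "- length", length(object@relevance), "\n")
})
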