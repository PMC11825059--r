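#' Append batch cluster centers to the memory bank
#'
#' All given centers are appended tagged with `batchIndex`; whenever more
#' than `capacityBatches` distinct batch indices are present the entries
#' of the oldest batch are evicted (strict FIFO over batch snapshots).
#' Labels absent from the batch simply contribute no entry. Stored
#' centers are detached history: no gradient ever flows through them.
#'
#' @param bank a [ClusterMemoryBank-class].
#' @param centers list with `labels` and `centers` as returned by
#'   [clusterCenters()] (an empty list leaves the bank unchanged).
#' @param batchIndex integer tag of the producing batch (must not
#'   decrease across calls).
#' @return the updated [ClusterMemoryBank-class].
#' @export
bankUpdate <- function(bank, centers, batchIndex) {
  stopifnot(is(bank, "ClusterMemoryBank"))
  if (length(centers$labels) == 0L) return(bank)
  if (ncol(centers$centers) != bank@dim) {
    stop("center dimension ", ncol(centers$centers),
         " does not match bank dimension ", bank@dim)
  }
  labels <- c(bank@labels, as.integer(centers$labels))
  mat <- rbind(bank@centers, centers$centers)
  bidx <- c(bank@batchIndex, rep(as.integer(batchIndex),
                                 length(centers$labels)))
  distinct <- unique(bidx)
  while (length(distinct) > bank@capacityBatches) {
    keep <- bidx != distinct[1L]
    labels <- labels[keep]
    mat <- mat[keep, , drop = FALSE]
    bidx <- bidx[keep]
    distinct <- distinct[-1L]
  }
  new("ClusterMemoryBank", dim = bank@dim,
      capacityBatches = bank@capacityBatches, labels = labels,
      centers = unname(mat), batchIndex = bidx)
}

#' Snapshot of the memory bank contents
#'
#' @param bank a [ClusterMemoryBank-class].
#' @return list with `labels` (integer vector) and `centers` (matrix, one
#'   row per entry) in insertion order; a copy, so mutating it leaves the
#'   bank intact.
#' @export
bankView <- function(bank) {
  stopifnot(is(bank, "ClusterMemoryBank"))
  list(labels = bank@labels, centers = bank@centers)
}

#' @describeIn bankView number of stored centers.
#' @export
bankSize <- function(bank) length(bank@labels)
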