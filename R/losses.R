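#' Contrastive loss configuration
#'
#' @param tau temperature (> 0, default 0.1).
#' @param warmupEpochs N_w, epochs with the cluster-level term disabled
#'   (default 0).
#' @param reduction `"sum"` (sum over anchors, the canonical objective) or
#'   `"mean"` (batch-size-robust alternative).
#' @param renormalizeCenters if `TRUE`, cluster centers are re-normalised
#'   to unit length before use (default `FALSE`: centers are plain means,
#'   so their dot products carry the cluster's concentration).
#' @return a validated `LossConfig` list.
#' @export
lossConfig <- function(tau = 0.1, warmupEpochs = 0L,
                       reduction = c("sum", "mean"),
                       renormalizeCenters = FALSE) {
  stopifnot(tau > 0, warmupEpochs >= 0)
  structure(list(tau = tau, warmupEpochs = as.integer(warmupEpochs),
                 reduction = match.arg(reduction),
                 renormalizeCenters = renormalizeCenters),
            class = "LossConfig")
}

.rowLogSumExp <- function(S) {
  mx <- apply(S, 1, max)
  mx + log(rowSums(exp(S - mx)))
}

#' Instance-level supervised contrastive loss
#'
#' For each anchor k (source embedding), the comparison set A(k) is every
#' target embedding of the batch including the anchor's own target view;
#' the positive set P(k) are the targets sharing the anchor's label
#' (always containing k itself, so the loss is defined even for singleton
#' classes). Per anchor:
#' `-(1/|P(k)|) * sum_{p in P(k)} log( exp(zs_k . zt_p / tau) /
#'  sum_{a in A(k)} exp(zs_k . zt_a / tau) )`,
#' computed with a log-sum-exp-stable denominator.
#'
#' @param batch an [EmbeddingBatch-class].
#' @param tau temperature (> 0).
#' @param gradient if `TRUE`, also return gradients of the summed loss
#'   with respect to `zSource` and `zTarget`.
#' @return list with `perAnchor` (length N), `total` (their sum), and,
#'   when requested, `gradSource` / `gradTarget` (`N x D`).
#' @export
instanceSupConLoss <- function(batch, tau, gradient = FALSE) {
  stopifnot(is(batch, "EmbeddingBatch"), tau > 0)
  zs <- batch@zSource
  zt <- batch@zTarget
  N <- nrow(zs)
  if (N == 0L) stop("empty batch")
  S <- (zs %*% t(zt)) / tau
  P <- outer(batch@labels, batch@labels, "==") * 1
  nPos <- rowSums(P)
  lse <- .rowLogSumExp(S)
  perAnchor <- -(rowSums(P * S) / nPos - lse)
  out <- list(perAnchor = as.numeric(perAnchor), total = sum(perAnchor))
  if (gradient) {
    soft <- exp(S - lse)                   # row softmax
    dS <- (soft - P / nPos) / tau
    out$gradSource <- dS %*% zt
    out$gradTarget <- t(dS) %*% zs
  }
  out
}

#' Per-class cluster centers of a batch
#'
#' Arithmetic (indicator-weighted) mean of each label's target embeddings.
#' Centers are not re-normalised; output is sorted by label id.
#'
#' @param zTarget numeric matrix `N x D` of target embeddings.
#' @param labels integer vector of length N.
#' @return list with `labels` (sorted unique labels) and `centers`
#'   (matrix, one row per label).
#' @export
clusterCenters <- function(zTarget, labels) {
  zTarget <- as.matrix(zTarget)
  stopifnot(nrow(zTarget) == length(labels), nrow(zTarget) >= 1L)
  labs <- sort(unique(as.integer(labels)))
  centers <- t(vapply(labs, function(lb) {
    colMeans(zTarget[labels == lb, , drop = FALSE])
  }, numeric(ncol(zTarget))))
  list(labels = labs, centers = centers)
}

#' Cluster-level supervised contrastive loss against the memory bank
#'
#' For each anchor, the comparison set is every center stored in the
#' bank; positives are the stored centers sharing the anchor's label.
#' Anchors with no positive in the bank contribute 0 and are counted in
#' `skipped`; an empty bank gives total 0 with all anchors skipped.
#'
#' @param zSource numeric matrix `N x D` of source (anchor) embeddings.
#' @param labels integer vector of length N.
#' @param bank a [ClusterMemoryBank-class].
#' @param tau temperature (> 0).
#' @param gradient if `TRUE`, also return the gradient w.r.t. `zSource`
#'   (bank entries are detached history: no gradient flows into them).
#' @param renormalizeCenters re-normalise centers to unit length first.
#' @return list with `perAnchor`, `total`, `skipped` and optionally
#'   `gradSource`.
#' @export
clusterSupConLoss <- function(zSource, labels, bank, tau, gradient = FALSE,
                              renormalizeCenters = FALSE) {
  stopifnot(is(bank, "ClusterMemoryBank"), tau > 0)
  zSource <- as.matrix(zSource)
  N <- nrow(zSource)
  view <- bankView(bank)
  if (length(view$labels) == 0L) {
    out <- list(perAnchor = numeric(N), total = 0, skipped = N)
    if (gradient) out$gradSource <- zSource * 0
    return(out)
  }
  centers <- view$centers
  if (renormalizeCenters) {
    nrm <- sqrt(rowSums(centers^2))
    nrm[nrm == 0] <- 1
    centers <- centers / nrm
  }
  S <- (zSource %*% t(centers)) / tau      # N x B
  P <- outer(as.integer(labels), view$labels, "==") * 1
  nPos <- rowSums(P)
  active <- nPos > 0
  lse <- .rowLogSumExp(S)
  perAnchor <- numeric(N)
  perAnchor[active] <- -(rowSums(P * S)[active] / nPos[active] - lse[active])
  out <- list(perAnchor = perAnchor, total = sum(perAnchor),
              skipped = sum(!active))
  if (gradient) {
    soft <- exp(S - lse)
    dS <- soft
    dS[active, ] <- dS[active, , drop = FALSE] -
      P[active, , drop = FALSE] / nPos[active]
    dS[!active, ] <- 0
    out$gradSource <- (dS / tau) %*% centers
  }
  out
}

#' Warm-up gate for the cluster-level term
#'
#' Returns 0 while `epoch <= warmupEpochs` and 1 afterwards (1-based
#' epochs): the cluster-level loss only engages once the bank holds
#' embeddings from a partly trained encoder.
#'
#' @param epoch 1-based epoch index.
#' @param warmupEpochs N_w (>= 0).
#' @return 0 or 1.
#' @export
alphaSchedule <- function(epoch, warmupEpochs) {
  stopifnot(epoch >= 1)
  if (epoch <= warmupEpochs) 0 else 1
}

#' Combined two-level contrastive objective
#'
#' `L = sum_k [ L_instance_k + alpha * L_cluster_k ]` with `alpha` from
#' [alphaSchedule()]; the reduction is a sum over anchors (a `"mean"`
#' alternative is available via `reduction`).
#'
#' @param batch an [EmbeddingBatch-class].
#' @param bank a [ClusterMemoryBank-class].
#' @param tau temperature.
#' @param epoch 1-based epoch index.
#' @param warmupEpochs N_w.
#' @param reduction `"sum"` or `"mean"`.
#' @param renormalizeCenters see [clusterSupConLoss()].
#' @return list with `total`, `instance`, `cluster`, `alpha`, `skipped`.
#' @export
combinedLoss <- function(batch, bank, tau, epoch, warmupEpochs,
                         reduction = "sum", renormalizeCenters = FALSE) {
  alpha <- alphaSchedule(epoch, warmupEpochs)
  ins <- instanceSupConLoss(batch, tau)
  clus <- if (alpha > 0) {
    clusterSupConLoss(batch@zSource, batch@labels, bank, tau,
                      renormalizeCenters = renormalizeCenters)
  } else {
    list(total = 0, skipped = nrow(batch@zSource))
  }
  scale <- if (reduction == "mean") 1 / nrow(batch@zSource) else 1
  list(total = scale * (ins$total + alpha * clus$total),
       instance = scale * ins$total, cluster = scale * clus$total,
       alpha = alpha, skipped = clus$skipped)
}
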