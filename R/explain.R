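#' Grad-CAM feature-map weights
#'
#' Importance of each final-layer feature map for the attributed class:
#' the mean over the temporal units of the gradient of the class score
#' (pre-softmax logit) with respect to that map's activations.
#'
#' @param gradients numeric `K x l` matrix of d(logit_c)/d(A_k(t)).
#' @return numeric vector of K weights.
#' @export
gradcamWeights <- function(gradients) {
  rowMeans(as.matrix(gradients))
}

#' Grad-CAM relevance map
#'
#' `relevance(t) = max(0, sum_k w_k * A_k(t))` — the ReLU keeps only
#' time steps whose weighted activation supports the class.
#'
#' @param activations numeric `K x l` matrix of feature-map activations.
#' @param weights numeric vector of K weights from [gradcamWeights()].
#' @param classId attributed zero-based class id (metadata).
#' @param caseId attributed case index (metadata).
#' @return an [AttributionMap-class] of length l.
#' @export
gradcamMap <- function(activations, weights, classId = NA_integer_,
                       caseId = NA_integer_) {
  activations <- as.matrix(activations)
  stopifnot(nrow(activations) == length(weights))
  rel <- pmax(0, colSums(activations * weights))
  new("AttributionMap", relevance = as.numeric(rel),
      classId = as.integer(classId), caseId = as.integer(caseId))
}

#' Grad-CAM time-step attribution for one case
#'
#' Forward-propagates the case to the class logit (softmax is bypassed:
#' adding a constant to all logits leaves the map unchanged),
#' back-propagates to the final convolutional feature maps, and combines
#' [gradcamWeights()] and [gradcamMap()]. The encoder preserves temporal
#' length, so the map aligns 1:1 with input time steps.
#'
#' @param net a trained `SupConNet`.
#' @param x one case, `m x l` matrix (or `1 x m x l` array).
#' @param classId zero-based class id to attribute (< nClasses).
#' @param caseId optional case index stored in the result.
#' @param rescale if `TRUE`, min-max scale the relevance to `[0, 1]` for
#'   display (the raw map is the default).
#' @return an [AttributionMap-class] of length l.
#' @export
gradcamAttribute <- function(net, x, classId, caseId = NA_integer_,
                             rescale = FALSE) {
  stopifnot(is(net, "SupConNet"))
  if (classId < 0L || classId >= net$cfg$nClasses) {
    stop("classId must be in 0..", net$cfg$nClasses - 1L)
  }
  eb <- .toEngine(x)
  if (eb$N != 1L) stop("attribution is per case; pass a single m x l case")
  fwd <- .encoderFwd(net, eb$x, eb$l, eb$N, FALSE)
  cl <- .mlpFwd(net, fwd$h, "cls")
  dlogits <- matrix(0, net$cfg$nClasses, 1L)
  dlogits[classId + 1L, 1L] <- 1
  dh <- .mlpBwd(net, cl, dlogits, "cls")$dh         # Dh x 1
  # GAP makes d(logit)/dA constant over time: dh / l for every unit
  grads <- matrix(dh, net$cfg$featureDim, eb$l) / eb$l
  A <- fwd$A
  dim(A) <- c(net$cfg$featureDim, eb$l)
  map <- gradcamMap(A, gradcamWeights(grads), classId, caseId)
  if (rescale) {
    r <- map@relevance
    span <- max(r) - min(r)
    if (span > 0) map@relevance <- (r - min(r)) / span
  }
  map
}
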