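#' Jittering augmentation specification
#'
#' The contrastive stage uses only additive Gaussian jitter: a
#' high-variance (strong) draw feeds the source branch and a low-variance
#' (weak) draw feeds the target branch. Noise is i.i.d. across channels
#' and time on z-normalised data; masked (padded) positions are never
#' jittered. Defaults put the two variances an order of magnitude apart.
#'
#' @param sigmaStrong jitter sd of the strong/source view (> 0, default 0.5).
#' @param sigmaWeak jitter sd of the weak/target view (>= 0, default 0.05).
#' @return a validated `AugmentationSpec` list.
#' @export
augmentSpec <- function(sigmaStrong = 0.5, sigmaWeak = 0.05) {
  stopifnot(sigmaStrong > 0, sigmaWeak >= 0)
  if (sigmaStrong < sigmaWeak) {
    stop("'sigmaStrong' must be >= 'sigmaWeak' (strong view is high-variance)")
  }
  structure(list(sigmaStrong = sigmaStrong, sigmaWeak = sigmaWeak),
            class = "AugmentationSpec")
}

#' Add Gaussian jitter to a series
#'
#' Returns `x + e` with `e ~ N(0, sigma^2)` i.i.d. per observed entry;
#' entries with mask 0 are left untouched at the fill value. Deterministic
#' given `rngSeed`.
#'
#' @param x numeric `m x l` matrix (one case) or `m x l x N` array (batch).
#' @param sigma noise sd (>= 0).
#' @param mask binary array of the same shape (default: all observed).
#' @param rngSeed optional integer; when given, seeds the draw.
#' @return jittered array of the same shape.
#' @export
jitterSeries <- function(x, sigma, mask = NULL, rngSeed = NULL) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (!is.null(mask) && !identical(dim(mask), dim(x))) {
    stop("'x' and 'mask' shapes must agree")
  }
  if (sigma == 0) return(x)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  eps <- array(stats::rnorm(length(x), 0, sigma), dim(x) %||% length(x))
  if (!is.null(mask)) eps[mask == 0] <- 0
  x + eps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the strong and weak augmented views of a batch
#'
#' Independent jitter draws: `xStrong = x + N(0, sigmaStrong^2)`,
#' `xWeak = x + N(0, sigmaWeak^2)`, masked entries untouched.
#'
#' @param x numeric `m x l` matrix or `m x l x N` batch array.
#' @param spec an [augmentSpec()].
#' @param mask binary array of the same shape, or `NULL`.
#' @param rngSeed optional integer seeding both draws (they remain
#'   independent of each other).
#' @return list with `strong` and `weak` arrays.
#' @export
makeViews <- function(x, spec, mask = NULL, rngSeed = NULL) {
  stopifnot(inherits(spec, "AugmentationSpec"))
  if (!is.null(rngSeed)) set.seed(rngSeed)
  list(strong = jitterSeries(x, spec$sigmaStrong, mask),
       weak = jitterSeries(x, spec$sigmaWeak, mask))
}
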