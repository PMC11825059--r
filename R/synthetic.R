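#' Derive an independent child seed from a master seed
#'
#' Lehmer-style integer mixing so that each pipeline stage (motif drawing,
#' noise, augmentation, shuffling, ...) gets its own reproducible stream
#' from one master seed. Results stay below 2^31.
#'
#' @param seed master seed (integer).
#' @param stream stream id (integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, stream) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% m)
  h <- (h * 48271 + (abs(as.numeric(stream)) %% m) + 1) %% m
  h <- (h * 69621 + 12345) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Specification of a synthetic class-structured MTSC dataset
#'
#' Classes are defined by smooth per-channel motifs (mixtures of
#' sinusoids with class-specific frequencies and phases). `interSim`
#' blends every class motif toward the across-class mean motif, shrinking
#' between-class distances; `nModesPerClass` gives each class several
#' sub-cluster motif variants (intra-class multimodality, the situation
#' the cluster-level contrastive term targets); `intraVar` is the sd of
#' i.i.d. Gaussian amplitude noise added per case; `raggedFrac` truncates
#' that fraction of cases to a random shorter length to exercise
#' padding/masking.
#'
#' @param nClasses number of classes, `>= 2`.
#' @param nPerClass cases per class.
#' @param m channels.
#' @param l series length.
#' @param intraVar sd of within-class per-point noise (default 0.3).
#' @param interSim motif overlap factor in `[0, 1)` (default 0).
#' @param nModesPerClass sub-cluster count per class (default 1).
#' @param raggedFrac fraction of cases truncated (default 0).
#' @param seed master seed.
#' @return a validated `SyntheticSpec` list.
#' @export
syntheticSpec <- function(nClasses = 2L, nPerClass = 50L, m = 3L, l = 64L,
                          intraVar = 0.3, interSim = 0,
                          nModesPerClass = 1L, raggedFrac = 0, seed = 1L) {
  stopifnot(nClasses >= 2L, nPerClass >= 1L, m >= 1L, l >= 4L,
            intraVar >= 0, interSim >= 0, interSim < 1,
            nModesPerClass >= 1L, raggedFrac >= 0, raggedFrac <= 1)
  structure(list(nClasses = as.integer(nClasses),
                 nPerClass = as.integer(nPerClass), m = as.integer(m),
                 l = as.integer(l), intraVar = intraVar, interSim = interSim,
                 nModesPerClass = as.integer(nModesPerClass),
                 raggedFrac = raggedFrac, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Class/mode motifs of a synthetic specification
#'
#' @param spec a [syntheticSpec()].
#' @return numeric array `nClasses x nModesPerClass x m x l` of the blended
#'   motifs actually used by [makeMTSC()].
#' @export
classMotifs <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(deriveSeed(spec$seed, 101L))
  tt <- seq_len(spec$l) / spec$l
  motifs <- array(0, c(spec$nClasses, spec$nModesPerClass, spec$m, spec$l))
  for (k in seq_len(spec$nClasses)) {
    for (j in seq_len(spec$m)) {
      f1 <- stats::runif(1, 1, 3); f2 <- stats::runif(1, 3, 6)
      ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
      for (q in seq_len(spec$nModesPerClass)) {
        # modes shift phases and re-weight harmonics within the class
        dq <- if (q == 1L) 0 else stats::runif(1, 0.8, 1.6) * (q - 1L)
        w <- if (q == 1L) 0.7 else stats::runif(1, 0.3, 0.9)
        motifs[k, q, j, ] <- w * sin(2 * pi * f1 * tt + ph1 + dq) +
          (1 - w) * sin(2 * pi * f2 * tt + ph2 - dq)
      }
    }
  }
  if (spec$interSim > 0) {
    meanMotif <- apply(motifs, c(3, 4), mean)  # across classes and modes
    for (k in seq_len(spec$nClasses)) {
      for (q in seq_len(spec$nModesPerClass)) {
        motifs[k, q, , ] <- (1 - spec$interSim) * motifs[k, q, , ] +
          spec$interSim * meanMotif
      }
    }
  }
  motifs
}

#' Generate a synthetic class-structured MTSC dataset
#'
#' Each case is the motif of a randomly chosen mode of its class plus
#' i.i.d. Gaussian noise of sd `intraVar`; a `raggedFrac` fraction of
#' cases is truncated to a random length in `[l/2, l - 1]` (padded
#' positions hold the fill value 0 with mask 0). Deterministic under
#' `spec$seed`.
#'
#' @param spec a [syntheticSpec()].
#' @return an [MTSCDataset-class] with `nClasses * nPerClass` cases.
#' @examples
#' ds <- makeMTSC(syntheticSpec(nClasses = 2, nPerClass = 5, seed = 7))
#' ds
#' @export
makeMTSC <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  motifs <- classMotifs(spec)
  n <- spec$nClasses * spec$nPerClass
  labels <- rep(seq_len(spec$nClasses) - 1L, each = spec$nPerClass)
  set.seed(deriveSeed(spec$seed, 202L))
  modes <- sample.int(spec$nModesPerClass, n, replace = TRUE)
  values <- array(0, c(n, spec$m, spec$l))
  for (i in seq_len(n)) {
    base <- motifs[labels[i] + 1L, modes[i], , , drop = TRUE]
    if (spec$m == 1L) base <- matrix(base, 1L, spec$l)
    noise <- if (spec$intraVar > 0) {
      matrix(stats::rnorm(spec$m * spec$l, 0, spec$intraVar), spec$m, spec$l)
    } else 0
    values[i, , ] <- base + noise
  }
  mask <- array(1, c(n, spec$m, spec$l))
  if (spec$raggedFrac > 0) {
    set.seed(deriveSeed(spec$seed, 303L))
    nRagged <- round(spec$raggedFrac * n)
    ragged <- sample.int(n, nRagged)
    lo <- max(2L, ceiling(spec$l / 2))
    for (i in ragged) {
      li <- sample(seq(lo, spec$l - 1L), 1L)
      values[i, , (li + 1L):spec$l] <- 0
      mask[i, , (li + 1L):spec$l] <- 0
    }
  }
  mtscDataset(values, mask, labels,
              classNames = paste0("class", seq_len(spec$nClasses) - 1L))
}

#' Generate a clustered embedding fixture on the unit hypersphere
#'
#' Class k concentrates around the canonical axis e_k; each instance has a
#' latent point `normalize(separation * e_k + g)`, `g ~ N(0, I)`, and the
#' paired source/target views are drawn around the same latent point with
#' the same concentration. `separation = Inf` yields exact orthogonal
#' class axes with zero within-class noise. Labels are balanced
#' round-robin.
#'
#' @param n number of instance pairs (`>= nClasses`).
#' @param d embedding dimension (`>= nClasses`).
#' @param nClasses number of classes.
#' @param separation concentration parameter (> 0, may be `Inf`).
#' @param seed integer seed.
#' @return an [EmbeddingBatch-class].
#' @export
makeEmbeddingFixture <- function(n, d, nClasses, separation, seed = 1L) {
  stopifnot(n >= nClasses, d >= 2, d >= nClasses, separation > 0)
  labels <- rep(seq_len(nClasses) - 1L, length.out = n)
  normalize <- function(x) x / sqrt(sum(x^2))
  set.seed(deriveSeed(seed, 404L))
  zs <- matrix(0, n, d); zt <- matrix(0, n, d)
  for (i in seq_len(n)) {
    axis <- numeric(d); axis[labels[i] + 1L] <- 1
    if (is.infinite(separation)) {
      zs[i, ] <- axis; zt[i, ] <- axis
    } else {
      latent <- normalize(separation * axis + stats::rnorm(d))
      zs[i, ] <- normalize(separation * latent + stats::rnorm(d))
      zt[i, ] <- normalize(separation * latent + stats::rnorm(d))
    }
  }
  embeddingBatch(zs, zt, labels)
}

#' Two-class dataset whose classes differ only inside a time window
#'
#' Localisation fixture for time-step attribution: both classes share the
#' same smooth base signal on every channel; class 1 additionally carries
#' a raised-cosine bump confined to `window` (1-based, inclusive). A
#' faithful attribution method should concentrate class-1 relevance
#' inside the window.
#'
#' @param n number of cases (balanced across the two classes).
#' @param m channels.
#' @param l series length.
#' @param window integer vector of the discriminative time steps
#'   (default `21:30`).
#' @param amplitude bump height (default 1.5).
#' @param noise sd of additive Gaussian noise (default 0.2).
#' @param seed integer seed.
#' @return an [MTSCDataset-class] with classes `same` (0) and `bump` (1).
#' @export
makeWindowedMTSC <- function(n, m = 2L, l = 48L, window = 21:30,
                             amplitude = 1.5, noise = 0.2, seed = 1L) {
  stopifnot(n >= 2L, max(window) <= l, min(window) >= 1L)
  set.seed(deriveSeed(seed, 505L))
  tt <- seq_len(l) / l
  base <- t(vapply(seq_len(m), function(j) {
    sin(2 * pi * stats::runif(1, 1, 2.5) * tt + stats::runif(1, 0, 2 * pi))
  }, numeric(l)))
  bump <- numeric(l)
  u <- (seq_along(window) - 1) / (length(window) - 1)
  bump[window] <- amplitude * 0.5 * (1 - cos(2 * pi * u))
  labels <- rep(c(0L, 1L), length.out = n)
  values <- array(0, c(n, m, l))
  for (i in seq_len(n)) {
    xi <- base
    if (labels[i] == 1L) xi <- xi + rep(bump, each = m)
    values[i, , ] <- xi + matrix(stats::rnorm(m * l, 0, noise), m, l)
  }
  mtscDataset(values, labels = labels, classNames = c("same", "bump"))
}
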