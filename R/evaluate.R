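#' Classification accuracy
#'
#' Fraction of exact matches (equals (TP+TN)/(TP+FP+TN+FN) in the binary
#' case).
#'
#' @param yTrue,yPred equal-length label vectors.
#' @return accuracy in `[0, 1]`.
#' @export
accuracyScore <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) {
    stop("'yTrue' and 'yPred' must have equal length")
  }
  if (length(yTrue) == 0L) stop("need at least one prediction")
  mean(yTrue == yPred)
}

#' Read an accuracy table (datasets x methods)
#'
#' CSV with dataset names in the first column and one column per method.
#' `-`, empty cells and `NA` are treated as missing (explicitly flagged,
#' never silently zero). Values must lie in `[0, 1]`.
#'
#' @param path CSV file path.
#' @return numeric matrix with dataset row names and method column names.
#' @export
readAccuracyTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  mat <- as.matrix(as.data.frame(lapply(df, function(col) {
    col[col %in% c("-", "")] <- NA
    as.numeric(col)
  }), check.names = FALSE))
  rownames(mat) <- rn
  ok <- is.na(mat) | (mat >= 0 & mat <= 1)
  if (!all(ok)) stop(path, ": accuracies must lie in [0, 1]")
  mat
}

#' Pairwise win/tie/loss counts between two methods
#'
#' Rows with a missing value in either column are excluded and reported.
#' Ties are exact equality of the tabulated values. Note the convention
#' that "method a outperforms b on W of n datasets" counts wins plus
#' ties.
#'
#' @param table numeric matrix from [readAccuracyTable()].
#' @param methodA,methodB column names.
#' @return list with `wins`, `ties`, `losses` (counts for `methodA`) and
#'   `excluded` (row names dropped for missingness).
#' @export
pairwiseWins <- function(table, methodA, methodB) {
  for (mm in c(methodA, methodB)) {
    if (!mm %in% colnames(table)) stop("unknown method '", mm, "'")
  }
  a <- table[, methodA]
  b <- table[, methodB]
  keep <- !is.na(a) & !is.na(b)
  list(wins = sum(a[keep] > b[keep]), ties = sum(a[keep] == b[keep]),
       losses = sum(a[keep] < b[keep]),
       excluded = rownames(table)[!keep])
}

.rankRows <- function(table) {
  # rank 1 = best accuracy; ties get mid-ranks
  t(apply(table, 1, function(r) rank(-r, ties.method = "average")))
}

#' Tie-corrected Friedman test over an accuracy table
#'
#' Per-dataset average ranks (rank 1 = highest accuracy, mid-ranks for
#' ties) and the tie-corrected Friedman chi-square statistic with its
#' p-value from the chi-square reference distribution. Rows containing a
#' missing value are dropped and reported.
#'
#' @param table numeric matrix (datasets x methods), >= 3 methods and
#'   >= 2 complete rows.
#' @return list with `statistic`, `pValue`, `meanRanks`, `df`, `nRows`,
#'   `excluded`.
#' @export
friedmanRankTest <- function(table) {
  keep <- stats::complete.cases(table)
  excluded <- rownames(table)[!keep]
  tb <- table[keep, , drop = FALSE]
  n <- nrow(tb); k <- ncol(tb)
  if (k < 3L) stop("need >= 3 methods")
  if (n < 2L) stop("need >= 2 complete rows")
  ranks <- .rankRows(tb)
  Rj <- colSums(ranks)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(ranks^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) {
    stat <- 0; p <- 1          # all rows completely tied
  } else {
    stat <- num / den
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = stat, pValue = p, meanRanks = Rj / n, df = k - 1,
       nRows = n, excluded = excluded)
}

.wilcoxonPrattP <- function(d) {
  # Pratt handling of zeros: rank |d| with zeros included, discard the
  # zero ranks, normal approximation with tie correction
  r <- rank(abs(d), ties.method = "average")
  nz <- d != 0
  if (!any(nz)) return(1)
  V <- sum(r[nz][d[nz] > 0])
  n <- length(d)
  EV <- sum(r[nz]) / 2
  ties <- table(r)
  varV <- sum(r[nz]^2) / 4
  z <- (V - EV) / sqrt(varV)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Pairwise Wilcoxon signed-rank tests with Holm correction
#'
#' Two-sided Wilcoxon signed-rank test on every method pair's
#' per-dataset accuracies (rows missing either value are dropped per
#' pair; zero differences are dropped by default, or handled by the
#' Pratt method), followed by Holm's step-down correction over the
#' m(m-1)/2 p-values at level `alpha`. Methods are grouped into cliques
#' by transitive grouping (connected components) of non-rejected pairs —
#' the solid bars of a critical-difference diagram.
#'
#' @param table numeric matrix (datasets x methods).
#' @param alpha family-wise level (default 0.05).
#' @param zeroMethod `"wilcox"` (drop zero differences) or `"pratt"`.
#' @return list with `pRaw` (symmetric matrix), `pHolm`, `reject`
#'   (logical matrix), `meanRanks` (over complete rows), `cliques`
#'   (list of character vectors) and `excluded` rows per pair.
#' @export
wilcoxonHolm <- function(table, alpha = 0.05,
                         zeroMethod = c("wilcox", "pratt")) {
  zeroMethod <- match.arg(zeroMethod)
  k <- ncol(table)
  if (k < 2L) stop("need >= 2 methods")
  methods <- colnames(table)
  pRaw <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  excluded <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- table[, i]; b <- table[, j]
      keep <- !is.na(a) & !is.na(b)
      excluded[[paste(methods[i], methods[j], sep = " vs ")]] <-
        rownames(table)[!keep]
      d <- a[keep] - b[keep]
      p <- if (all(d == 0)) {
        1
      } else if (zeroMethod == "pratt") {
        .wilcoxonPrattP(d)
      } else {
        suppressWarnings(stats::wilcox.test(a[keep], b[keep],
                                            paired = TRUE)$p.value)
      }
      pRaw[i, j] <- pRaw[j, i] <- p
    }
  }
  ut <- upper.tri(pRaw)
  pHolm <- pRaw
  pHolm[ut] <- stats::p.adjust(pRaw[ut], method = "holm")
  pHolm[lower.tri(pHolm)] <- t(pHolm)[lower.tri(pHolm)]
  reject <- !is.na(pHolm) & pHolm < alpha
  diag(reject) <- FALSE
  # transitive grouping of non-rejected pairs
  comp <- seq_len(k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!reject[i, j]) comp[comp == comp[j]] <- comp[i]
    }
  }
  cliques <- lapply(unique(comp), function(ci) methods[comp == ci])
  complete <- stats::complete.cases(table)
  meanRanks <- if (sum(complete) >= 1L) {
    colMeans(.rankRows(table[complete, , drop = FALSE]))
  } else rep(NA_real_, k)
  names(meanRanks) <- methods
  list(pRaw = pRaw, pHolm = pHolm, reject = reject,
       meanRanks = meanRanks, cliques = cliques, excluded = excluded,
       alpha = alpha)
}
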