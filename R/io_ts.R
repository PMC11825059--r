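#' Pad ragged multivariate series and build an observation mask
#'
#' Cases of unequal length are right-padded to the longest length. Padded
#' positions, and positions that are `NaN`/`NA` inside a series (missing
#' observations), receive mask 0; observed positions keep their value and
#' receive mask 1. Padded positions hold `missingSentinel` until the
#' dataset is finalised by [znormalize()], which replaces them with 0.
#'
#' @param ragged list of per-case numeric matrices, each `m x l_i` with a
#'   common channel count m.
#' @param missingSentinel value written at padded positions (default `NaN`).
#' @return list with `values` (`n x m x lMax` array) and `mask` (same shape,
#'   1 = observed, 0 = padded/missing).
#' @examples
#' r <- list(matrix(1:6, 2), matrix(1:10, 2))
#' padAndMask(r)$mask[1, 1, ]
#' @export
padAndMask <- function(ragged, missingSentinel = NaN) {
  if (length(ragged) == 0L) stop("'ragged' must contain at least one case")
  ms <- vapply(ragged, nrow, integer(1))
  if (length(unique(ms)) != 1L) {
    stop("all cases must share the channel count; got m = ",
         paste(unique(ms), collapse = ", "))
  }
  m <- ms[1L]
  ls <- vapply(ragged, ncol, integer(1))
  if (any(ls < 1L)) stop("every case must have length >= 1")
  lMax <- max(ls)
  n <- length(ragged)
  values <- array(missingSentinel, c(n, m, lMax))
  mask <- array(0, c(n, m, lMax))
  for (i in seq_len(n)) {
    xi <- ragged[[i]]
    li <- ncol(xi)
    obs <- is.finite(xi)
    values[i, , seq_len(li)] <- xi
    mask[i, , seq_len(li)] <- obs * 1
    # interior missing values keep the sentinel, not the NA they came with
    if (!all(obs)) {
      v <- values[i, , seq_len(li), drop = FALSE]
      v[!obs] <- missingSentinel
      values[i, , seq_len(li)] <- v
    }
  }
  list(values = values, mask = mask)
}

.parseError <- function(path, lineNo, msg) {
  stop(sprintf("%s:%d: %s", path, lineNo, msg), call. = FALSE)
}

#' Read a sktime/UEA ".ts" (or ARFF) multivariate time series file
#'
#' Parses the sktime dialect: `@`-prefixed header lines (tabs and spaces
#' both tolerated, keys case-insensitive), then `@data`, then one line per
#' case with channels separated by `:` and the class label as the final
#' field. `?` marks a missing value. Plain ARFF files (one row per case,
#' last attribute the class) are delegated to [foreign::read.arff()] and
#' read as single-channel series. Ragged cases are padded via
#' [padAndMask()]; class names map to ids `0..c-1` in sorted lexicographic
#' order, fixed across splits.
#'
#' @param path file path.
#' @param split `"train"` or `"test"`. For a test split, pass the training
#'   split's `classNames` so unseen labels raise an error rather than
#'   silently extending the mapping.
#' @param classNames optional character vector fixing the label universe
#'   (required semantics for `split = "test"`).
#' @return An [MTSCDataset-class]; padded/missing positions hold `NaN`
#'   until [znormalize()] finalises them.
#' @export
readTsFile <- function(path, split = c("train", "test"), classNames = NULL) {
  split <- match.arg(split)
  if (grepl("\\.arff$", path, ignore.case = TRUE) && !.looksLikeTs(path)) {
    return(.readArffAsDataset(path, split, classNames))
  }
  lines <- readLines(path, warn = FALSE)
  headerLabels <- NULL
  dataStart <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(tolower(ln), "@data")) { dataStart <- i + 1L; break }
    if (startsWith(ln, "@")) {
      toks <- strsplit(ln, "[ \t]+")[[1]]
      key <- tolower(sub("^@", "", toks[1L]))
      if (key == "classlabel") {
        if (length(toks) < 2L) {
          .parseError(path, i, "malformed @classLabel header")
        }
        if (tolower(toks[2L]) == "true") headerLabels <- toks[-(1:2)]
      }
      next
    }
    .parseError(path, i, sprintf("unexpected line before @data: '%s'", ln))
  }
  if (is.na(dataStart)) .parseError(path, length(lines), "no @data section")

  ragged <- list()
  rawLabels <- character()
  mSeen <- NA_integer_
  for (i in seq(dataStart, length.out = max(0L, length(lines) - dataStart + 1L))) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      .parseError(path, i, "data line needs at least one channel and a label")
    }
    lab <- trimws(parts[length(parts)])
    chans <- parts[-length(parts)]
    if (!is.na(mSeen) && length(chans) != mSeen) {
      .parseError(path, i, sprintf(
        "case has %d channels but previous cases have %d",
        length(chans), mSeen))
    }
    mSeen <- length(chans)
    vals <- lapply(seq_along(chans), function(j) {
      toks <- trimws(strsplit(chans[[j]], ",", fixed = TRUE)[[1]])
      v <- suppressWarnings(as.numeric(ifelse(toks == "?", NA, toks)))
      bad <- which(is.na(v) & toks != "?" & toks != "NaN" & toks != "NA")
      if (length(bad)) {
        .parseError(path, i, sprintf(
          "channel %d: cannot parse value '%s'", j, toks[bad[1L]]))
      }
      v
    })
    li <- max(vapply(vals, length, integer(1)))
    xi <- matrix(NaN, mSeen, li)
    for (j in seq_along(vals)) xi[j, seq_along(vals[[j]])] <- vals[[j]]
    ragged[[length(ragged) + 1L]] <- xi
    rawLabels <- c(rawLabels, lab)
  }
  if (length(ragged) == 0L) .parseError(path, length(lines), "no data rows")

  universe <- classNames
  if (is.null(universe)) universe <- headerLabels
  if (is.null(universe)) universe <- unique(rawLabels)
  universe <- sort(universe)  # deterministic id mapping across splits
  unknown <- setdiff(rawLabels, universe)
  if (length(unknown)) {
    stop(sprintf(
      "%s: unknown class label(s) in %s split: %s", path, split,
      paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  pm <- padAndMask(ragged)
  mtscDataset(pm$values, pm$mask,
              labels = match(rawLabels, universe) - 1L,
              classNames = universe)
}

.looksLikeTs <- function(path) {
  head <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                   error = function(e) character())
  any(grepl("^@(problemName|seriesLength|dimensions|univariate|classLabel)",
            head, ignore.case = TRUE))
}

.readArffAsDataset <- function(path, split, classNames) {
  df <- foreign::read.arff(path)
  classCol <- which(vapply(df, is.factor, logical(1)))
  if (length(classCol) == 0L) {
    stop(path, ": ARFF file has no nominal class attribute", call. = FALSE)
  }
  classCol <- classCol[length(classCol)]
  rawLabels <- as.character(df[[classCol]])
  x <- as.matrix(df[, -classCol, drop = FALSE])
  ragged <- lapply(seq_len(nrow(x)), function(i) matrix(x[i, ], nrow = 1L))
  universe <- if (is.null(classNames)) sort(unique(rawLabels)) else sort(classNames)
  unknown <- setdiff(rawLabels, universe)
  if (length(unknown)) {
    stop(sprintf("%s: unknown class label(s) in %s split: %s", path, split,
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  pm <- padAndMask(ragged)
  mtscDataset(pm$values, pm$mask, labels = match(rawLabels, universe) - 1L,
              classNames = universe)
}

#' Read the documented long CSV format
#'
#' Columns `case_id, channel, t, value, label` (header required). Each case
#' must provide the same set of channels; time indices `t` are 1-based and
#' may stop early for ragged cases.
#'
#' @param path CSV file path.
#' @return An [MTSCDataset-class].
#' @export
readLongCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "channel", "t", "value", "label")
  if (!all(need %in% names(df))) {
    stop(path, ": CSV must have columns ", paste(need, collapse = ", "))
  }
  caseIds <- unique(df$case_id)
  chans <- sort(unique(df$channel))
  rawLabels <- character(length(caseIds))
  ragged <- vector("list", length(caseIds))
  for (i in seq_along(caseIds)) {
    sub <- df[df$case_id == caseIds[[i]], , drop = FALSE]
    if (!setequal(unique(sub$channel), chans)) {
      stop(path, ": case ", caseIds[[i]], " is missing channels")
    }
    li <- max(sub$t)
    xi <- matrix(NaN, length(chans), li)
    xi[cbind(match(sub$channel, chans), sub$t)] <- sub$value
    ragged[[i]] <- xi
    rawLabels[i] <- as.character(sub$label[1L])
  }
  universe <- sort(unique(rawLabels))
  pm <- padAndMask(ragged)
  mtscDataset(pm$values, pm$mask, labels = match(rawLabels, universe) - 1L,
              classNames = universe)
}

#' Write an MTSCDataset to a ".ts" file
#'
#' Writes the sktime dialect read back by [readTsFile()]. Trailing padded
#' positions of a case are omitted per channel; interior missing positions
#' are written as `?`.
#'
#' @param ds an [MTSCDataset-class].
#' @param path output file path.
#' @param problemName string written to the `@problemName` header.
#' @return `path`, invisibly.
#' @export
writeTsFile <- function(ds, path, problemName = "dataset") {
  v <- ds@values
  msk <- ds@mask
  n <- dim(v)[1L]; m <- dim(v)[2L]; l <- dim(v)[3L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("@problemName ", problemName),
    "@timeStamps false",
    "@missing true",
    paste0("@univariate ", if (m == 1L) "true" else "false"),
    paste0("@dimensions ", m),
    "@equalLength false",
    paste0("@classLabel true ", paste(ds@classNames, collapse = " ")),
    "@data"), con)
  for (i in seq_len(n)) {
    chanStrs <- vapply(seq_len(m), function(j) {
      mi <- msk[i, j, ]
      li <- if (any(mi == 1)) max(which(mi == 1)) else 1L
      vals <- v[i, j, seq_len(li)]
      toks <- format(vals, trim = TRUE, digits = 17)
      toks[mi[seq_len(li)] == 0] <- "?"
      paste(toks, collapse = ",")
    }, character(1))
    writeLines(paste0(paste(chanStrs, collapse = ":"), ":",
                      ds@classNames[ds@labels[i] + 1L]), con)
  }
  invisible(path)
}

#' Per-channel z-normalisation with masked statistics
#'
#' Each channel is transformed to `(x - mean) / sd` with mean and sd
#' computed over observed (mask = 1) positions only, pooled across cases
#' and time. The sd has a floor of `1e-8` so constant channels are safe.
#' Padded/missing positions are then set to the fill value 0 (the channel
#' mean post-normalisation, inert under convolution), finalising the
#' dataset. Pass the returned `stats` to normalise a test split with the
#' training split's statistics.
#'
#' @param ds an [MTSCDataset-class].
#' @param stats optional `data.frame(mean, sd)` with one row per channel,
#'   as returned by a previous call (training-split statistics).
#' @return list with `dataset` (finalised [MTSCDataset-class]) and `stats`.
#' @export
znormalize <- function(ds, stats = NULL) {
  v <- ds@values
  msk <- ds@mask
  m <- dim(v)[2L]
  if (is.null(stats)) {
    mu <- numeric(m); sdv <- numeric(m)
    for (j in seq_len(m)) {
      obs <- v[, j, ][msk[, j, ] == 1]
      mu[j] <- mean(obs)
      sdv[j] <- max(stats::sd(obs), 1e-8)
      if (is.na(sdv[j])) sdv[j] <- 1e-8  # single observed point
    }
    stats <- data.frame(mean = mu, sd = sdv)
  } else {
    if (nrow(stats) != m) stop("'stats' must have one row per channel")
  }
  for (j in seq_len(m)) {
    v[, j, ] <- (v[, j, ] - stats$mean[j]) / stats$sd[j]
  }
  v[msk == 0] <- 0
  out <- mtscDataset(v, msk, ds@labels, ds@classNames, ds@channelNames)
  list(dataset = out, stats = stats)
}

#' Cache a dataset to a single-file archive
#'
#' Serialises values, mask, labels and names to one RDS file (the package's
#' dataset cache format).
#'
#' @param ds an [MTSCDataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveDataset <- function(ds, path) {
  saveRDS(list(schema = "SupConTSC/dataset/1", values = ds@values,
               mask = ds@mask, labels = ds@labels,
               classNames = ds@classNames, channelNames = ds@channelNames),
          path)
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "SupConTSC/dataset/1")) {
    stop(path, ": not a SupConTSC dataset cache")
  }
  mtscDataset(x$values, x$mask, x$labels, x$classNames, x$channelNames)
}
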