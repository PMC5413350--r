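#' @include AllClasses.R AllGenerics.R
NULL

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors robust to composition differences. The
#' reference sample is the one whose 75th-percentile count fraction is
#' closest to the mean across samples. For each sample, gene-wise log2
#' count-fraction ratios against the reference (M) and average log2
#' abundances (A) are computed over genes positive in both libraries;
#' the upper and lower `trimM` of M values and `trimA` of A values are
#' trimmed; the factor is 2 to the precision-weighted mean of the
#' surviving M values (weights: inverse asymptotic binomial variances).
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param x counts matrix (genes x samples) or
#'   [DualSeqExperiment-class].
#' @param trimM trim fraction for M values, each tail (default 0.30).
#' @param trimA trim fraction for A values, each tail (default 0.05).
#' @param refColumn optional reference sample (index or name);
#'   otherwise chosen by the 75th-percentile rule.
#' @return a data.frame with one row per sample: `sample`, `lib_size`,
#'   `tmm_factor`, `effective_size` (= lib_size x tmm_factor).
#' @export
#' @examples
#' m <- matrix(rpois(400, 50), 100, 4,
#'             dimnames = list(NULL, paste0("s", 1:4)))
#' tmmFactors(m)
tmmFactors <- function(x, trimM = 0.30, trimA = 0.05, refColumn = NULL) {
  if (is(x, "DualSeqExperiment")) x <- counts(x)
  stopifnot(is.matrix(x), ncol(x) >= 2, all(x >= 0))
  libSize <- colSums(x)
  zero <- which(libSize == 0)
  if (length(zero))
    stop("sample with all-zero counts: ",
         colnames(x)[zero[1]] %||% zero[1])
  f75 <- vapply(seq_len(ncol(x)), function(j)
    stats::quantile(x[, j], 0.75) / libSize[j], 0)
  if (is.null(refColumn))
    refColumn <- which.min(abs(f75 - mean(f75)))
  if (is.character(refColumn)) refColumn <- match(refColumn, colnames(x))
  pr <- x[, refColumn] / libSize[refColumn]
  fac <- vapply(seq_len(ncol(x)), function(j) {
    if (j == refColumn) return(1)
    pt <- x[, j] / libSize[j]
    keep <- pt > 0 & pr > 0
    if (!any(keep)) return(1)
    M <- log2(pt[keep] / pr[keep])
    A <- 0.5 * log2(pt[keep] * pr[keep])
    # inverse asymptotic binomial variance of M
    w <- 1 / ((1 - pt[keep]) / (x[keep, j]) +
                (1 - pr[keep]) / (x[keep, refColumn]))
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - (floor(n * trimM) + 1)
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - (floor(n * trimA) + 1)
    rM <- rank(M)
    rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel)) return(1)
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }, 0)
  fac <- fac / exp(mean(log(fac)))
  smp <- colnames(x) %||% sprintf("sample%d", seq_len(ncol(x)))
  data.frame(sample = smp, lib_size = libSize, tmm_factor = fac,
             effective_size = libSize * fac, row.names = smp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn cpm CPM from a counts matrix and (optionally) TMM
#'   normalization factors; with `norm = NULL` raw library sizes are
#'   used.
#' @param norm a data.frame from [tmmFactors()], or `NULL`.
#' @export
setMethod("cpm", "matrix", function(x, norm = NULL) {
  eff <- if (is.null(norm)) colSums(x)
         else norm$effective_size[match(colnames(x) %||% norm$sample,
                                        norm$sample)]
  if (any(eff <= 0)) stop("non-positive effective library size")
  sweep(x, 2, eff / 1e6, "/")
})

#' @describeIn cpm CPM from a [DualSeqExperiment-class].
#' @export
setMethod("cpm", "DualSeqExperiment", function(x, norm = NULL) {
  cpm(counts(x), norm = norm)
})

#' Two-sample Kolmogorov-Smirnov test for library-prep GC bias
#'
#' Compares the GC-content distribution of transcripts detected under
#' both library preparations with that of transcripts detected under
#' only one: a significant difference indicates prep-dependent GC bias
#' (e.g. loss of high-GC transcripts under a low-input protocol).
#'
#' @param gcShared GC fractions of transcripts detected in both preps.
#' @param gcExclusive GC fractions detected in only one prep.
#' @return list with elements `statistic` (D) and `p.value`
#'   (asymptotic).
#' @export
gcBiasTest <- function(gcShared, gcExclusive) {
  if (length(gcShared) < 2 || length(gcExclusive) < 2)
    stop("each group needs at least 2 values")
  kt <- suppressWarnings(stats::ks.test(gcShared, gcExclusive,
                                        exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

.binByQuantile <- function(v, nBins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(br) < 3) stop("degenerate bin boundaries")
  list(bin = cut(v, br, include.lowest = TRUE, labels = FALSE),
       breaks = br)
}

.smoothAdjacent <- function(m) {
  # running mean over adjacent bins (window 3, truncated at the ends)
  nb <- nrow(m)
  out <- m
  for (b in seq_len(nb)) {
    i <- max(1, b - 1):min(nb, b + 1)
    out[b, ] <- colMeans(m[i, , drop = FALSE])
  }
  out
}

#' Fit quantile-bin GC (and length) offsets
#'
#' Approximates conditional-quantile GC correction with additive
#' median-polish offsets: genes are grouped into GC quantile bins
#' (deciles by default); the offset of a bin in a sample is the median
#' log-CPM deviation of that bin from the bin's cross-sample median,
#' smoothed across adjacent bins and re-centred so the per-sample
#' offsets are zero-sum (weighted by bin occupancy). The resulting
#' offsets feed the negative-binomial GLM as additions to the log
#' effective library size, removing GC-by-prep covariation from
#' cross-prep contrasts. Length offsets are fitted analogously when
#' `lengthBins > 0`.
#'
#' @param x counts matrix (genes x samples) or
#'   [DualSeqExperiment-class].
#' @param gc per-gene GC fraction (taken from `rowData` for a
#'   `DualSeqExperiment`).
#' @param lengthBp per-gene length in bp (optional; only used when
#'   `lengthBins > 0`).
#' @param nBins number of GC quantile bins (default 10).
#' @param lengthBins number of length bins (default 0 = no length
#'   model).
#' @param smooth smooth offsets across adjacent bins (default TRUE).
#' @return a [GCOffsetModel-class].
#' @export
fitGCOffsets <- function(x, gc = NULL, lengthBp = NULL, nBins = 10,
                         lengthBins = 0, smooth = TRUE) {
  if (is(x, "DualSeqExperiment")) {
    gc <- gc %||% gcFraction(x)
    lengthBp <- lengthBp %||% lengthBp(x)
    x <- counts(x)
  }
  stopifnot(is.matrix(x), length(gc) == nrow(x))
  if (nrow(x) / nBins < 10) stop("too few genes")
  lib <- colSums(x)
  logCpm <- log((sweep(x, 2, lib, "/") * 1e6) + 0.5)
  fitOne <- function(covariate, nb) {
    bn <- .binByQuantile(covariate, nb)
    nbEff <- length(bn$breaks) - 1
    med <- matrix(0, nbEff, ncol(x))
    cntB <- tabulate(bn$bin, nbEff)
    for (b in seq_len(nbEff)) {
      rows <- bn$bin == b
      med[b, ] <- apply(logCpm[rows, , drop = FALSE], 2, stats::median)
    }
    dev <- med - apply(med, 1, stats::median)
    if (smooth) dev <- .smoothAdjacent(dev)
    # zero-sum per sample, weighted by bin occupancy
    dev <- sweep(dev, 2, colSums(dev * cntB) / sum(cntB), "-")
    colnames(dev) <- colnames(x)
    list(breaks = bn$breaks, offsets = dev, counts = cntB)
  }
  g <- fitOne(gc, nBins)
  l <- if (lengthBins > 0) {
    stopifnot(!is.null(lengthBp))
    fitOne(log(lengthBp), lengthBins)
  } else NULL
  new("GCOffsetModel", gcBreaks = g$breaks, gcOffsets = g$offsets,
      gcBinCounts = as.numeric(g$counts),
      lengthBreaks = if (is.null(l)) NULL else l$breaks,
      lengthOffsets = if (is.null(l)) NULL else l$offsets,
      lengthBinCounts = if (is.null(l)) NULL else as.numeric(l$counts))
}

#' Expand a GC offset model to a per-observation offset matrix
#'
#' @param model a [GCOffsetModel-class].
#' @param gc per-gene GC fraction.
#' @param lengthBp per-gene length (only needed when the model carries
#'   length offsets).
#' @return genes x samples matrix of natural-log offsets, to be added to
#'   log effective library sizes in the GLM.
#' @export
offsetMatrix <- function(model, gc, lengthBp = NULL) {
  stopifnot(is(model, "GCOffsetModel"))
  bin <- cut(gc, model@gcBreaks, include.lowest = TRUE, labels = FALSE)
  bin[is.na(bin)] <- ifelse(gc[is.na(bin)] < model@gcBreaks[1], 1,
                            nrow(model@gcOffsets))
  out <- model@gcOffsets[bin, , drop = FALSE]
  if (!is.null(model@lengthBreaks)) {
    stopifnot(!is.null(lengthBp))
    lb <- cut(log(lengthBp), model@lengthBreaks, include.lowest = TRUE,
              labels = FALSE)
    lb[is.na(lb)] <- ifelse(log(lengthBp[is.na(lb)]) < model@lengthBreaks[1],
                            1, nrow(model@lengthOffsets))
    out <- out + model@lengthOffsets[lb, , drop = FALSE]
  }
  rownames(out) <- names(gc)
  out
}

#' Bin-slope GC trend diagnostic
#'
#' A simple analogue of quantile-regression bias plots: bins genes by GC
#' content and regresses the bin-median log ratio between two groups of
#' samples on the bin-mean GC. A slope near 0 (and small correlation)
#' indicates no residual GC-by-group trend.
#'
#' @param logRatio per-gene log expression ratio between the two groups
#'   being compared.
#' @param gc per-gene GC fraction.
#' @param nBins number of GC bins (default 10).
#' @return list with `slope`, `correlation` (Pearson r between GC and
#'   log ratio across genes), and the per-bin data.frame `bins`.
#' @export
gcTrend <- function(logRatio, gc, nBins = 10) {
  ok <- is.finite(logRatio) & is.finite(gc)
  logRatio <- logRatio[ok]; gc <- gc[ok]
  bn <- .binByQuantile(gc, nBins)
  df <- data.frame(
    gc = vapply(split(gc, bn$bin), mean, 0),
    ratio = vapply(split(logRatio, bn$bin), stats::median, 0))
  list(slope = unname(stats::coef(stats::lm(ratio ~ gc, df))[2]),
       correlation = stats::cor(gc, logRatio),
       bins = df)
}
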