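#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn fpkm FPKM from a counts matrix, per-gene lengths (bp) and
#'   per-sample library sizes.
#' @param lengthBp per-gene transcript length in bp.
#' @param librarySize per-sample library size in reads; defaults to the
#'   column sums of the counts.
#' @export
setMethod("fpkm", "matrix", function(x, lengthBp,
                                     librarySize = colSums(x)) {
  stopifnot(length(lengthBp) == nrow(x),
            length(librarySize) == ncol(x))
  if (any(librarySize <= 0)) stop("zero library size")
  if (any(lengthBp <= 0)) stop("non-positive transcript length")
  sweep(x / (lengthBp / 1e3), 2, librarySize / 1e6, "/")
})

#' @describeIn fpkm FPKM from a [DualSeqExperiment-class] (lengths from
#'   `rowData`, library sizes from column sums).
#' @export
setMethod("fpkm", "DualSeqExperiment", function(x, ...) {
  fpkm(counts(x), lengthBp = lengthBp(x), ...)
})

#' Sliding-window curve over expression-sorted genes
#'
#' Sorts genes ascending by their reference-condition statistic (stable;
#' ties broken by gene id), slides a window of `window` genes in steps of
#' `step`, and records for each window the median of the reference values
#' and a companion statistic: the median of a companion expression vector
#' (`statistic = "median"`, the lower-limit mode) or the proportion of a
#' logical companion (`statistic = "proportion"`, the absence-call mode).
#'
#' @param valuesRef named numeric, per-gene mean FPKM in the sorting
#'   condition.
#' @param companion per-gene companion statistic aligned with
#'   `valuesRef` (numeric, or logical for `"proportion"`).
#' @param window window width in genes (default 100).
#' @param step window step; 1 gives fully overlapping windows.
#' @param statistic companion summary: `"median"` or `"proportion"`.
#' @return a data.frame with columns `index` (window start in the sorted
#'   order), `refMedian` (non-decreasing) and `companion`.
#' @export
#' @examples
#' v <- stats::setNames(1:150, sprintf("g%03d", 1:150))
#' nrow(windowCurve(v, v, window = 100))  # 51 windows
windowCurve <- function(valuesRef, companion, window = 100, step = 1,
                        statistic = c("median", "proportion")) {
  statistic <- match.arg(statistic)
  n <- length(valuesRef)
  stopifnot(length(companion) == n, step >= 1)
  if (window < 2) stop("window must be >= 2")
  if (window > n) stop("window exceeds the number of genes")
  ids <- names(valuesRef)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(n))
  ord <- order(valuesRef, ids)
  vr <- valuesRef[ord]
  cp <- companion[ord]
  starts <- seq.int(1L, n - window + 1L, by = step)
  refMed <- vapply(starts, function(s)
    stats::median(vr[s:(s + window - 1L)]), 0)
  compStat <- if (statistic == "median")
    vapply(starts, function(s) stats::median(cp[s:(s + window - 1L)]), 0)
  else
    vapply(starts, function(s) mean(as.logical(cp[s:(s + window - 1L)])), 0)
  out <- data.frame(index = starts, refMedian = refMed,
                    companion = compStat)
  attr(out, "statistic") <- statistic
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Detect the correlation-onset lower expression limit
#'
#' Automates the visual rule for where between-condition correlation of
#' window medians sets in: scanning runs of `runLength` consecutive
#' windows, the onset is the earliest window from which Kendall's tau
#' between reference and companion medians is positive over every
#' subsequent run. Genes below the returned reference-median FPKM are
#' too shallow (or too stochastic) to compare between the conditions.
#'
#' @param curve a window curve from [windowCurve()] in `"median"` mode.
#' @param runLength run length: the number of windows entering each
#'   tau (default 20).
#' @param stride spacing, in curve rows, between the windows entering
#'   one tau. The default spaces them so a run spans about two window
#'   widths of genes: local enough not to straddle the onset, spaced
#'   enough that the median-to-median drift dominates the noise shared
#'   between overlapping windows; capped so a run always fits. Run
#'   *starts* are evaluated at every curve row, so the onset is located
#'   at single-window resolution.
#' @return the lower-limit FPKM (the onset window's reference median);
#'   `+Inf` with attribute `failed = TRUE` when no onset exists.
#'   Attribute `window` carries the onset window's row index.
#' @export
detectLowerLimit <- function(curve, runLength = 20, stride = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("refMedian", "companion") %in% colnames(curve)))
  nw <- nrow(curve)
  if (runLength > nw) stop("runLength exceeds the number of windows")
  if (runLength < 2) stop("runLength must be >= 2")
  if (is.null(stride)) {
    w <- attr(curve, "window") %||% 1
    s <- attr(curve, "step") %||% 1
    stride <- max(1, round(w / (s * runLength)))
  }
  stride <- max(1L, min(as.integer(stride),
                        (nw - 1L) %/% (runLength - 1L)))
  nRuns <- nw - (runLength - 1L) * stride
  tau <- vapply(seq_len(nRuns), function(s) {
    i <- s + stride * (0:(runLength - 1L))
    suppressWarnings(stats::cor(curve$refMedian[i], curve$companion[i],
                                method = "kendall"))
  }, 0)
  positive <- !is.na(tau) & tau > 0   # undefined tau (ties) is not evidence
  bad <- which(!positive)
  wstar <- if (!length(bad)) 1L else max(bad) + 1L
  # an onset must be backed by a sustained correlated regime: at least
  # `minTailSpans` non-overlapping runs beyond it must all be positive,
  # otherwise a chance block of positive taus at the tail of an
  # uncorrelated curve would masquerade as an onset
  minTailSpans <- 3L
  span <- (runLength - 1L) * stride + 1L
  if (wstar > 1L && (nRuns - wstar + 1L) < minTailSpans * span)
    wstar <- nRuns + 1L
  if (wstar > nRuns) {
    out <- Inf
    attr(out, "failed") <- TRUE
    attr(out, "window") <- NA_integer_
    return(out)
  }
  out <- curve$refMedian[wstar]
  attr(out, "failed") <- FALSE
  attr(out, "window") <- wstar
  out
}

#' Detect the absence-call threshold from a detection-proportion curve
#'
#' Builds the detection-proportion window curve (fraction of genes with
#' nonzero counts in every sample of the shallow condition, as a
#' function of deep-condition expression) and returns the smallest
#' reference-median FPKM above which every window reaches the detection
#' target. Below the threshold an absence call in the shallow condition
#' may be sequencing-depth dropout; above it, an absence is interpreted
#' as biological.
#'
#' @param fpkmRef per-gene mean FPKM in the deep condition (named).
#' @param detected per-gene logical: nonzero count in every sample of
#'   the shallow condition.
#' @param window window width (>= 10; default 100).
#' @param detectionTarget required detection proportion (default 0.95).
#' @param step window step (default 1).
#' @return the absence-call FPKM threshold (0 when every gene is
#'   detected, `+Inf` with attribute `failed = TRUE` when even the
#'   highest-expression windows miss the target). The window curve is
#'   attached as attribute `curve`.
#' @export
detectAbsenceThreshold <- function(fpkmRef, detected, window = 100,
                                   detectionTarget = 0.95, step = 1) {
  stopifnot(is.logical(detected), length(detected) == length(fpkmRef))
  if (window < 10) stop("window must be >= 10")
  if (detectionTarget <= 0 || detectionTarget > 1)
    stop("detectionTarget must lie in (0, 1]")
  if (all(detected)) {
    out <- 0
    attr(out, "failed") <- FALSE
    return(out)
  }
  curve <- windowCurve(fpkmRef, detected, window = window, step = step,
                       statistic = "proportion")
  failing <- curve$refMedian[curve$companion < detectionTarget]
  if (!length(failing)) {
    out <- min(curve$refMedian)
  } else {
    cand <- curve$refMedian[curve$refMedian > max(failing)]
    if (!length(cand)) {
      out <- Inf
      attr(out, "failed") <- TRUE
      attr(out, "curve") <- curve
      return(out)
    }
    out <- min(cand)
  }
  attr(out, "failed") <- FALSE
  attr(out, "curve") <- curve
  out
}

#' Apply the absence-call filter
#'
#' Removes genes that are undetected in the shallow condition and whose
#' deep-condition FPKM is strictly below the threshold (their absence is
#' attributable to depth); every detected gene, and every undetected
#' gene at or above the threshold (a biologically meaningful absence),
#' is retained.
#'
#' @param genes character vector of gene ids.
#' @param fpkmRef per-gene deep-condition mean FPKM, aligned with
#'   `genes`.
#' @param detected per-gene logical, aligned with `genes`.
#' @param threshold FPKM threshold from [detectAbsenceThreshold()].
#' @return the retained subset of `genes`.
#' @export
applyAbsenceFilter <- function(genes, fpkmRef, detected, threshold) {
  stopifnot(length(fpkmRef) == length(genes),
            length(detected) == length(genes))
  genes[detected | fpkmRef >= threshold]
}

#' Estimate the full threshold set for a dual RNA-seq experiment
#'
#' Learns the four condition-wise lower limits (host-only and
#' host-plus-symbiont over the host gene set; capsule and intracellular
#' over the symbiont gene set, the intracellular signal being the
#' symbiont genes of the host-plus-symbiont samples) and the
#' absence-call threshold for the shallow intracellular condition.
#' Mean-across-replicates FPKM is used both for sorting and for
#' threshold comparison.
#'
#' @param x a [DualSeqExperiment-class].
#' @param hostGenes,symbiontGenes gene id vectors (e.g. from
#'   [classifyByBestHit()]).
#' @param window,step,runLength,detectionTarget see [windowCurve()],
#'   [detectLowerLimit()] and [detectAbsenceThreshold()].
#' @return a [ThresholdSet-class].
#' @export
estimateThresholds <- function(x, hostGenes, symbiontGenes, window = 100,
                               step = 1, runLength = 20,
                               detectionTarget = 0.95) {
  stopifnot(is(x, "DualSeqExperiment"))
  fk <- fpkm(x)
  cls <- sampleClass(x)
  meanBy <- function(genes, klass) {
    rowMeans(fk[genes, cls == klass, drop = FALSE])
  }
  curves <- list()
  ll <- c(host_only = NA_real_, host_plus_symbiont = NA_real_,
          capsule_symbiont = NA_real_, intracellular_symbiont = NA_real_)
  pairs <- list(
    host_only = list(genes = hostGenes, ref = "host_only",
                     other = "host_plus_symbiont"),
    host_plus_symbiont = list(genes = hostGenes,
                              ref = "host_plus_symbiont",
                              other = "host_only"),
    capsule_symbiont = list(genes = symbiontGenes,
                            ref = "capsule_symbiont",
                            other = "host_plus_symbiont"),
    intracellular_symbiont = list(genes = symbiontGenes,
                                  ref = "host_plus_symbiont",
                                  other = "capsule_symbiont"))
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (!length(p$genes) || !any(cls == p$ref) || !any(cls == p$other))
      next
    if (length(p$genes) < window) next
    cv <- windowCurve(meanBy(p$genes, p$ref), meanBy(p$genes, p$other),
                      window = window, step = step)
    curves[[nm]] <- cv
    ll[[nm]] <- as.numeric(detectLowerLimit(cv, runLength = runLength))
  }
  abs_thr <- NA_real_
  if (length(symbiontGenes) >= window && any(cls == "capsule_symbiont") &&
      any(cls == "host_plus_symbiont")) {
    ref <- meanBy(symbiontGenes, "capsule_symbiont")
    det <- rowSums(counts(x)[symbiontGenes, cls == "host_plus_symbiont",
                             drop = FALSE] > 0) ==
      sum(cls == "host_plus_symbiont")
    thr <- detectAbsenceThreshold(ref, det, window = window,
                                  detectionTarget = detectionTarget,
                                  step = step)
    curves[["absence"]] <- attr(thr, "curve")
    abs_thr <- as.numeric(thr)
  }
  new("ThresholdSet", lowerLimits = ll, absenceThreshold = abs_thr,
      detectionTarget = detectionTarget, window = as.numeric(window),
      curves = curves)
}
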