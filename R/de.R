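#' @include AllClasses.R normalization.R
#' @useDynLib symbioseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Build full/reduced design matrices for a (possibly paired) two-group
# comparison. condition is a factor with the reference level first.
.deDesign <- function(condition, pair = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2)
    stop("exactly two condition levels required")
  if (!is.null(pair) && !all(is.na(pair))) {
    pair <- as.factor(pair)
    tab <- table(pair, condition)
    if (any(tab == 0))
      stop("paired mode requires every pair to contain both conditions")
    full <- stats::model.matrix(~ pair + condition)
    reduced <- stats::model.matrix(~ pair)
  } else {
    full <- stats::model.matrix(~ condition)
    reduced <- stats::model.matrix(~ 1, data.frame(condition))
  }
  if (qr(full)$rank < ncol(full)) stop("design matrix is not full rank")
  list(full = full, reduced = reduced)
}

.offsetFor <- function(counts, norm = NULL, gcOffsets = NULL) {
  eff <- if (is.null(norm)) colSums(counts)
         else norm$effective_size[match(colnames(counts) %||% norm$sample,
                                        norm$sample)]
  if (anyNA(eff) || length(eff) != ncol(counts))
    stop("normalization factors do not cover every sample")
  off <- matrix(log(eff), nrow(counts), ncol(counts), byrow = TRUE,
                dimnames = dimnames(counts))
  if (!is.null(gcOffsets)) {
    stopifnot(identical(dim(gcOffsets), dim(off)))
    off <- off + gcOffsets
  }
  off
}

#' Fit a negative-binomial log-linear GLM to one gene
#'
#' Iteratively reweighted least squares with log link, per-observation
#' log offsets and fixed dispersion; convergence when the relative
#' deviance change falls below `tol` (default 1e-8) or after `maxit`
#' iterations. Non-convergence is flagged, not raised. An all-zero gene
#' gets zero coefficients and a converged flat fit.
#'
#' @param y integer counts for one gene (length = samples).
#' @param design design matrix (samples x coefficients).
#' @param offset per-observation natural-log offsets (log effective
#'   library size, plus GC offsets when used).
#' @param dispersion NB dispersion (>= 0; 0 = Poisson).
#' @param tol,maxit IRLS convergence tolerance / iteration cap.
#' @return list: `coefficients` (natural-log scale), `log2fc` (the last
#'   coefficient divided by log 2 — the condition coefficient in the
#'   designs built by [runDE()]), `loglik`, `deviance`, `converged`,
#'   `iter`.
#' @export
fitGeneGLM <- function(y, design, offset = rep(0, length(y)),
                       dispersion = 0, tol = 1e-8, maxit = 100) {
  stopifnot(length(y) == nrow(design), dispersion >= 0)
  fit <- .nbGlmFit(matrix(as.numeric(y), 1), design,
                   matrix(offset, 1), dispersion, tol, maxit)
  cf <- drop(fit$coefficients)
  names(cf) <- colnames(design)
  list(coefficients = cf, log2fc = unname(cf[length(cf)]) / log(2),
       loglik = fit$loglik[1], deviance = fit$deviance[1],
       converged = fit$converged[1], iter = fit$iter[1])
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximises the mean Cox-Reid adjusted profile
#' log-likelihood (APL) across genes, located on a log-spaced grid and
#' refined by golden-section search. Tagwise dispersions maximise each
#' gene's own APL plus `priorDf` times the mean APL curve — an
#' empirical-Bayes compromise that shrinks gene-wise estimates toward
#' the common value, completely so as `priorDf` grows to infinity.
#'
#' @param counts genes x samples count matrix.
#' @param condition,pair sample condition labels (2 levels) and optional
#'   pair ids (see [runDE()]).
#' @param priorDf prior degrees of freedom for shrinkage (default 10).
#' @param offset optional per-observation log-offset matrix.
#' @param gridRange log10 range of the dispersion grid.
#' @param gridLength number of grid points.
#' @return a [DispersionEstimates-class].
#' @export
estimateDispersions <- function(counts, condition, pair = NULL,
                                priorDf = 10, offset = NULL,
                                gridRange = c(-4, 0.7),
                                gridLength = 15) {
  condition <- as.factor(condition)
  if (min(table(condition)) < 2 && (is.null(pair) || all(is.na(pair))))
    stop("at least 2 samples per condition (or pairing) required")
  d <- .deDesign(condition, pair)
  X <- d$full
  if (is.null(offset))
    offset <- matrix(log(colSums(counts)), nrow(counts), ncol(counts),
                     byrow = TRUE)
  phiGrid <- 10^seq(gridRange[1], gridRange[2], length.out = gridLength)
  apl <- .nbAplGrid(counts, X, offset, phiGrid)
  meanApl <- colMeans(apl)
  k <- which.max(meanApl)
  lo <- phiGrid[max(1, k - 1)]; hi <- phiGrid[min(length(phiGrid), k + 1)]
  opt <- stats::optimize(function(lp)
    .nbAplAt(counts, X, offset, 10^lp),
    lower = log10(lo), upper = log10(hi), maximum = TRUE, tol = 1e-3)
  common <- 10^opt$maximum
  # tagwise: per-gene argmax of APL_g + priorDf * mean APL on the grid,
  # sharpened by quadratic interpolation on log10(phi)
  crit <- apl + matrix(priorDf * meanApl, nrow(apl), ncol(apl),
                       byrow = TRUE)
  lg <- log10(phiGrid)
  tagwise <- vapply(seq_len(nrow(crit)), function(g) {
    i <- which.max(crit[g, ])
    if (i == 1 || i == length(lg)) return(10^lg[i])
    y3 <- crit[g, (i - 1):(i + 1)]
    x3 <- lg[(i - 1):(i + 1)]
    den <- (y3[1] - 2 * y3[2] + y3[3])
    if (!is.finite(den) || den >= 0) return(10^lg[i])
    10^(x3[2] - 0.5 * (x3[3] - x3[1]) / 2 * (y3[3] - y3[1]) / den)
  }, 0)
  zeroGene <- rowSums(counts) == 0
  tagwise[zeroGene] <- common
  names(tagwise) <- rownames(counts)
  new("DispersionEstimates", common = common, tagwise = tagwise,
      priorDf = priorDf)
}

#' Likelihood-ratio test between nested GLM fits
#'
#' @param full,reduced fits of the full and the nested reduced model
#'   (per-gene lists from [fitGeneGLM()], or vectors of log-likelihoods
#'   with an attribute-free numeric interface via `llFull`/`llReduced`).
#' @param llFull,llReduced alternatively, numeric log-likelihood vectors.
#' @param dfDiff difference in number of coefficients.
#' @return list of vectors `statistic` (2 x delta log-likelihood) and
#'   `p.value` (upper-tail chi-square with `dfDiff` degrees of freedom).
#' @export
likelihoodRatioTest <- function(full = NULL, reduced = NULL,
                                llFull = NULL, llReduced = NULL,
                                dfDiff = 1) {
  if (is.null(llFull)) llFull <- full$loglik
  if (is.null(llReduced)) llReduced <- reduced$loglik
  stat <- 2 * (llFull - llReduced)
  if (any(stat < -1e-4, na.rm = TRUE))
    stop("negative LR statistic beyond tolerance: fit failure")
  stat <- pmax(stat, 0)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = dfDiff, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, order-preserving).
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full differential expression test
#'
#' Paired (when `pair` is given) negative-binomial GLM likelihood-ratio
#' test per gene: dispersions are estimated with empirical-Bayes
#' shrinkage ([estimateDispersions()]), full and reduced models are fit
#' with per-observation offsets (log effective library size from TMM,
#' plus optional GC offsets), and p-values are FDR-adjusted by
#' Benjamini-Hochberg. Genes that fail IRLS convergence are kept with
#' p = 1 (conservative); all-zero genes report log2FC 0, p 1.
#'
#' @param counts genes x samples count matrix (or
#'   [DualSeqExperiment-class], in which case `condition`/`pair` may be
#'   column-data names).
#' @param condition two-level factor over samples; the second level is
#'   the numerator of the fold change.
#' @param pair optional pair ids (blocking factor) or NULL.
#' @param norm optional [tmmFactors()] output; default TMM on `counts`.
#' @param gcOffsets optional genes x samples natural-log offset matrix
#'   from [offsetMatrix()].
#' @param dispersion optional fixed dispersion(s); default estimated.
#' @param priorDf shrinkage prior df (default 10).
#' @param alpha FDR significance level (default 0.05).
#' @return a data.frame (one row per gene): `gene`, `log2fc`,
#'   `lr_statistic`, `p_value`, `fdr`, `direction` (`up`/`down`),
#'   `significant`, `converged`; the per-contrast tally is attached as
#'   attribute `summary`.
#' @export
runDE <- function(counts, condition, pair = NULL, norm = NULL,
                  gcOffsets = NULL, dispersion = NULL, priorDf = 10,
                  alpha = 0.05) {
  if (is(counts, "DualSeqExperiment")) counts <- counts(counts)
  stopifnot(is.matrix(counts), alpha > 0, alpha < 1)
  if (is.null(norm)) norm <- tmmFactors(counts)
  off <- .offsetFor(counts, norm, gcOffsets)
  d <- .deDesign(condition, pair)
  if (is.null(dispersion)) {
    disp <- estimateDispersions(counts, condition, pair,
                                priorDf = priorDf, offset = off)
    phi <- disp@tagwise
  } else {
    phi <- rep_len(dispersion, nrow(counts))
  }
  fitF <- .nbGlmFit(counts, d$full, off, phi)
  fitR <- .nbGlmFit(counts, d$reduced, off, phi)
  lrt <- likelihoodRatioTest(llFull = fitF$loglik,
                             llReduced = fitR$loglik,
                             dfDiff = ncol(d$full) - ncol(d$reduced))
  log2fc <- fitF$coefficients[, ncol(d$full)] / log(2)
  p <- lrt$p.value
  allZero <- rowSums(counts) == 0
  failed <- !(fitF$converged & fitR$converged)
  p[failed | allZero] <- 1
  log2fc[allZero] <- 0
  fdr <- bhAdjust(p)
  res <- data.frame(
    gene = rownames(counts) %||% sprintf("g%d", seq_len(nrow(counts))),
    log2fc = log2fc, lr_statistic = lrt$statistic, p_value = p,
    fdr = fdr,
    direction = ifelse(log2fc > 0, "up", "down"),
    significant = fdr < alpha & !allZero,
    converged = !failed, row.names = NULL)
  nSig <- sum(res$significant)
  attr(res, "summary") <- data.frame(
    tested = nrow(res), total = nSig,
    up = sum(res$significant & res$direction == "up"),
    down = sum(res$significant & res$direction == "down"),
    alpha = alpha)
  res
}
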