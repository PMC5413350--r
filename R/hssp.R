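#' @include AllClasses.R
NULL

#' HSSP percent-identity threshold curve
#'
#' The homology-derived structure of proteins (HSSP) curve gives, for an
#' alignment of length L, the percent identity above which homology
#' reliably implies structural/functional similarity: 100 for L <= 11;
#' `nOffset + 480 * L^(-0.32 * (1 + exp(-L / 1000)))` for 11 < L <= 450;
#' and the asymptote `nOffset + 19.5` beyond 450 residues (the two
#' branches agree to better than 0.1 at the junction).
#'
#' @param alignmentLength alignment length(s) in residues (>= 1).
#' @param nOffset additive curve offset n (default 0, the base curve).
#' @return percent-identity threshold(s).
#' @export
#' @examples
#' hsspCurve(c(5, 100, 500))
hsspCurve <- function(alignmentLength, nOffset = 0) {
  L <- alignmentLength
  if (any(L < 1)) stop("alignment length must be >= 1")
  out <- ifelse(L <= 11, 100,
         ifelse(L <= 450,
                nOffset + 480 * L^(-0.32 * (1 + exp(-L / 1000))),
                nOffset + 19.5))
  unname(out)
}

#' HSSP distance of hits from the curve
#'
#' @param percentIdentity,alignmentLength hit alignment statistics.
#' @param nOffset curve offset passed to [hsspCurve()].
#' @return signed distance `percentIdentity - hsspCurve(alignmentLength)`.
#' @export
hsspDistance <- function(percentIdentity, alignmentLength, nOffset = 0) {
  percentIdentity - hsspCurve(alignmentLength, nOffset)
}

#' Filter functional annotations by HSSP distance
#'
#' Discards hits whose HSSP distance is `<= minDist` (strictly greater
#' than `minDist` is required to retain — a hit sitting exactly on the
#' margin is dropped) and assigns each gene the surviving hit with the
#' maximal HSSP distance; exact ties are broken by subject id
#' lexicographic order, so the assignment is deterministic.
#'
#' @param hits data.frame with columns `qseqid`, `sseqid`, `pident`,
#'   `length` (BLAST tabular naming).
#' @param minDist minimum HSSP distance (default 5).
#' @param nOffset curve offset passed to [hsspCurve()].
#' @return list with `annotations` (one row per annotated gene: the
#'   assigned best hit) and `hits` (all input hits with `hssp_dist` and
#'   `retained` columns).
#' @export
filterAnnotations <- function(hits, minDist = 5, nOffset = 0) {
  stopifnot(is.data.frame(hits),
            all(c("qseqid", "sseqid", "pident", "length") %in%
                  colnames(hits)))
  hits$hssp_dist <- hsspDistance(hits$pident, hits$length, nOffset)
  hits$retained <- hits$hssp_dist > minDist
  surv <- hits[hits$retained, , drop = FALSE]
  if (nrow(surv)) {
    surv <- surv[order(surv$qseqid, -surv$hssp_dist, surv$sseqid), ,
                 drop = FALSE]
    best <- surv[!duplicated(surv$qseqid), , drop = FALSE]
    rownames(best) <- NULL
  } else {
    best <- surv
  }
  list(annotations = best, hits = hits)
}
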