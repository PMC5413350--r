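#' @include AllClasses.R
NULL

.GROUP2LABEL <- c(plant_or_green_alga = "symbiont",
                  animal_or_vertebrate = "host",
                  fungal = "contaminant", mite = "contaminant",
                  other = "unknown")

#' Classify transcripts by best-hit taxon voting
#'
#' For each query the hit with maximal bitscore determines the label:
#' best hits to plant or green-algal subjects become `symbiont`, to
#' animal/vertebrate subjects `host`, and to fungal or mite subjects
#' `contaminant` (discarded downstream). Queries with no hits are
#' `unknown` and can be rescued by expression pattern
#' ([rescueUnknowns()]). An exact bitscore tie between hits that imply
#' conflicting labels yields `ambiguous`; ambiguous transcripts are
#' reported but excluded from both gene sets.
#'
#' @param hits data.frame of hit records with columns `qseqid`,
#'   `sseqid`, `bitscore`, `alignment` columns and `taxon_group` (attach
#'   the group via [readHitTable()]'s subject map when reading BLAST
#'   tabular output).
#' @param transcriptIds optional character vector of all transcripts
#'   under classification; ids absent from `hits` are labelled
#'   `unknown`. Defaults to the queries present in `hits`.
#' @return an assignment data.frame with columns `transcript_id`,
#'   `label` and `evidence` (best-hit subject and bitscore, or a rule
#'   id), one row per transcript.
#' @export
classifyByBestHit <- function(hits, transcriptIds = NULL) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits)) {
    if (any(!is.finite(hits$bitscore)))
      stop("non-finite bitscore for query ",
           hits$qseqid[which(!is.finite(hits$bitscore))[1]])
    bad <- which(hits$length < 1)
    if (length(bad))
      stop("malformed record (alignment length < 1) for query ",
           hits$qseqid[bad[1]])
    if (!all(hits$taxon_group %in% .TAXON_GROUPS))
      stop("unknown taxon_group in hit table")
  }
  if (is.null(transcriptIds)) transcriptIds <- unique(hits$qseqid)
  res <- data.frame(transcript_id = transcriptIds,
                    label = "unknown", evidence = "no_hit",
                    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    sp <- split(hits, hits$qseqid)
    lab <- vapply(sp, function(h) {
      top <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
      labs <- unique(.GROUP2LABEL[top$taxon_group])
      # hits to groups mapping to the same label (e.g. fungal + mite) agree
      if (length(labs) > 1L) "ambiguous" else labs
    }, "")
    ev <- vapply(sp, function(h) {
      top <- h[which.max(h$bitscore), , drop = FALSE]
      sprintf("best_hit:%s:%s:%.1f", top$taxon_group, top$sseqid,
              top$bitscore)
    }, "")
    m <- match(names(sp), res$transcript_id)
    ok <- !is.na(m)
    res$label[m[ok]] <- lab[ok]
    res$evidence[m[ok]] <- ev[ok]
  }
  res
}

#' Rescue no-homology transcripts by their expression pattern
#'
#' Transcripts without homology evidence are assigned by where they are
#' expressed: `symbiont` if expressed above the capsule-symbiont lower
#' limit in every capsule sample and below the host-only lower limit in
#' every host-only sample; `host` if the mirror-image pattern holds;
#' otherwise they stay `unknown`.
#'
#' @param unknowns character vector of transcript ids to rescue.
#' @param x a [DualSeqExperiment-class] containing those transcripts.
#' @param thresholds a [ThresholdSet-class] with lower limits named
#'   `host_only` and `capsule_symbiont`.
#' @return assignment data.frame (`transcript_id`, `label`, `evidence`).
#' @export
rescueUnknowns <- function(unknowns, x, thresholds) {
  stopifnot(is(x, "DualSeqExperiment"), is(thresholds, "ThresholdSet"))
  cls <- sampleClass(x)
  for (need in c("host_only", "capsule_symbiont"))
    if (!any(cls == need))
      stop("no samples of class '", need, "' in the experiment")
  ll <- lowerLimits(thresholds)
  stopifnot(all(c("host_only", "capsule_symbiont") %in% names(ll)))
  fk <- fpkm(x)[unknowns, , drop = FALSE]
  caps <- fk[, cls == "capsule_symbiont", drop = FALSE]
  host <- fk[, cls == "host_only", drop = FALSE]
  symPattern <- rowSums(caps > ll[["capsule_symbiont"]]) == ncol(caps) &
    rowSums(host < ll[["host_only"]]) == ncol(host)
  hostPattern <- rowSums(host > ll[["host_only"]]) == ncol(host) &
    rowSums(caps < ll[["capsule_symbiont"]]) == ncol(caps)
  label <- ifelse(symPattern, "symbiont",
                  ifelse(hostPattern, "host", "unknown"))
  data.frame(transcript_id = unknowns, label = label,
             evidence = ifelse(label == "unknown", "no_hit",
                               paste0("expression_pattern:", label)),
             stringsAsFactors = FALSE)
}

#' Combine homology and expression-pattern assignments
#'
#' Runs [classifyByBestHit()] over the hit table, then rescues the
#' `unknown` remainder with [rescueUnknowns()]. Every transcript of the
#' experiment receives exactly one label.
#'
#' @inheritParams rescueUnknowns
#' @param hits hit table (see [classifyByBestHit()]).
#' @return assignment data.frame covering `rownames(x)`.
#' @export
partitionCatalog <- function(x, hits, thresholds) {
  asg <- classifyByBestHit(hits, transcriptIds = rownames(x))
  unk <- asg$transcript_id[asg$label == "unknown"]
  if (length(unk)) {
    res <- rescueUnknowns(unk, x, thresholds)
    m <- match(res$transcript_id, asg$transcript_id)
    asg$label[m] <- res$label
    asg$evidence[m] <- res$evidence
  }
  asg
}

#' Build the symbiont gene set for differential expression
#'
#' A symbiont-labelled gene enters the analysis set if it has at least
#' one read pair in every capsule-symbiont sample or at least one in
#' every host-plus-symbiont sample, its FPKM clears the symbiont lower
#' limit in the samples of the presence clause it satisfies, and its
#' FPKM stays below the host-only lower limit in all host-only samples
#' (so it is not a misassigned host transcript).
#'
#' @param x a [DualSeqExperiment-class].
#' @param assignments assignment table from [partitionCatalog()] or
#'   [classifyByBestHit()].
#' @param thresholds a [ThresholdSet-class] with lower limits named
#'   `host_only`, `capsule_symbiont` and `intracellular_symbiont`.
#' @return character vector of retained symbiont gene ids.
#' @export
buildSymbiontGeneSet <- function(x, assignments, thresholds) {
  stopifnot(is(x, "DualSeqExperiment"), is(thresholds, "ThresholdSet"))
  if (nrow(assignments) == 0) stop("empty assignment table")
  ll <- lowerLimits(thresholds)
  cls <- sampleClass(x)
  sym <- assignments$transcript_id[assignments$label == "symbiont"]
  sym <- intersect(sym, rownames(x))
  if (!length(sym)) return(character(0))
  cnt <- counts(x)[sym, , drop = FALSE]
  fk <- fpkm(x)[sym, , drop = FALSE]
  caps <- cls == "capsule_symbiont"
  hps <- cls == "host_plus_symbiont"
  ho <- cls == "host_only"
  presentCaps <- rowSums(cnt[, caps, drop = FALSE] >= 1) == sum(caps)
  presentIntra <- if (any(hps))
    rowSums(cnt[, hps, drop = FALSE] >= 1) == sum(hps) else FALSE
  aboveCaps <- rowSums(fk[, caps, drop = FALSE] >
                         ll[["capsule_symbiont"]]) == sum(caps)
  aboveIntra <- if (any(hps) && "intracellular_symbiont" %in% names(ll))
    rowSums(fk[, hps, drop = FALSE] >
              ll[["intracellular_symbiont"]]) == sum(hps) else FALSE
  belowHost <- if (any(ho))
    rowSums(fk[, ho, drop = FALSE] < ll[["host_only"]]) == sum(ho) else TRUE
  keep <- ((presentCaps & aboveCaps) | (presentIntra & aboveIntra)) &
    belowHost
  sym[keep]
}
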