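#' @include AllClasses.R rng.R
NULL

# Solve the beta shape so that the rescaled distribution has exactly the
# requested median. GC is modelled as 0.2 + 0.6 * Beta(a, k - a): unimodal
# on [0.2, 0.8], matching the shapes of typical transcriptome GC histograms.
.betaShapeForMedian <- function(median_gc, concentration = 10) {
  u <- (median_gc - 0.2) / 0.6
  if (u <= 0 || u >= 1)
    stop("target median GC must lie strictly inside (0.2, 0.8)")
  f <- function(a)
    suppressWarnings(stats::qbeta(0.5, a, concentration - a)) - u
  a <- stats::uniroot(f, c(0.05, concentration - 0.05), tol = 1e-10)$root
  c(shape1 = a, shape2 = concentration - a)
}

.rgc <- function(n, median_gc, concentration = 10) {
  sh <- .betaShapeForMedian(median_gc, concentration)
  0.2 + 0.6 * stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
}

#' Simulate a mixed host/symbiont transcript catalog
#'
#' Draws transcript lengths (log-normal, floored at 100 bp) and GC
#' fractions per organism. GC is beta-distributed rescaled to
#' \[0.2, 0.8\] and calibrated so the population median equals the target:
#' by default 0.43 for the low-GC host and 0.62 for the high-GC symbiont,
#' the separation that makes library-prep GC bias organism-specific.
#' Contaminants are split evenly between a fungal and a mite taxon.
#'
#' @param nHost,nSymbiont,nContaminant transcript counts per organism.
#' @param gcMedians named numeric: target median GC per organism class.
#' @param gcConcentration beta concentration (shape1 + shape2).
#' @param meanLengthBp median transcript length in bp.
#' @param lengthSdLog sd of log length.
#' @param seed integer seed; identical seeds give identical catalogs.
#' @return a [TranscriptCatalog-class].
#' @export
#' @examples
#' cat <- simulateCatalog(nHost = 50, nSymbiont = 30, seed = 1)
#' table(organism(cat))
simulateCatalog <- function(nHost = 10000, nSymbiont = 5000,
                            nContaminant = 200,
                            gcMedians = c(host = 0.43, symbiont = 0.62,
                                          contaminant = 0.50),
                            gcConcentration = 10,
                            meanLengthBp = 1200, lengthSdLog = 0.7,
                            seed = 1L) {
  stopifnot(nHost >= 0, nSymbiont >= 0, nContaminant >= 0)
  if (nHost + nSymbiont + nContaminant == 0) stop("empty catalog")
  nFung <- nContaminant %/% 2
  nMite <- nContaminant - nFung
  org <- rep(c("host", "symbiont", "contaminant_fungus", "contaminant_mite"),
             c(nHost, nSymbiont, nFung, nMite))
  n <- length(org)
  withStream(seed, "catalog", "", {
    gc <- numeric(n)
    gc[org == "host"] <- .rgc(nHost, gcMedians[["host"]], gcConcentration)
    gc[org == "symbiont"] <- .rgc(nSymbiont, gcMedians[["symbiont"]],
                                  gcConcentration)
    ncont <- nFung + nMite
    gc[grepl("^contaminant", org)] <-
      .rgc(ncont, gcMedians[["contaminant"]], gcConcentration)
    len <- pmax(100L, as.integer(round(
      stats::rlnorm(n, log(meanLengthBp), lengthSdLog))))
  })
  pre <- c(host = "HOST", symbiont = "SYMB",
           contaminant_fungus = "FUNG", contaminant_mite = "MITE")
  idx <- stats::ave(seq_len(n), org, FUN = seq_along)
  ids <- sprintf("%s_%06d", pre[org], idx)
  new("TranscriptCatalog",
      DataFrame(transcript_id = ids, organism = org, length_bp = len,
                gc_fraction = gc, row.names = ids))
}

#' Simulate a paired dual RNA-seq study design
#'
#' Emulates the study layout this package targets: `nPairs` embryos each
#' contributing one host-only and one host-plus-symbiont sample (shared
#' `pair_id`), `nCapsule` free-living capsule symbiont samples, and
#' optionally `nCultured` cultured symbiont samples prepared with a
#' different library protocol (`"standard"` vs `"low_input"`), which is
#' what introduces the cross-prep GC bias.
#'
#' @param nPairs number of host sample pairs (default 4).
#' @param nCapsule number of capsule symbiont samples (default 3).
#' @param nCultured number of cultured symbiont samples (default 0).
#' @param depths named target sequencing depths (read pairs) per class.
#' @return a `DataFrame` sample sheet (one row per sample).
#' @export
simulateDesign <- function(nPairs = 4, nCapsule = 3, nCultured = 0,
                           depths = c(host_only = 1e7,
                                      host_plus_symbiont = 1e7,
                                      capsule_symbiont = 3e7,
                                      cultured_symbiont = 3e7)) {
  stopifnot(nPairs >= 0, nCapsule >= 0, nCultured >= 0, all(depths > 0))
  rows <- list()
  for (i in seq_len(nPairs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("host_E%d", i), sample_class = "host_only",
      pair_id = sprintf("E%d", i), library_prep = "low_input",
      target_depth = depths[["host_only"]])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("hostsym_E%d", i),
      sample_class = "host_plus_symbiont", pair_id = sprintf("E%d", i),
      library_prep = "low_input",
      target_depth = depths[["host_plus_symbiont"]])
  }
  for (i in seq_len(nCapsule))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("capsule_%d", i),
      sample_class = "capsule_symbiont", pair_id = NA_character_,
      library_prep = "low_input", target_depth = depths[["capsule_symbiont"]])
  for (i in seq_len(nCultured))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("culture_%d", i),
      sample_class = "cultured_symbiont", pair_id = NA_character_,
      library_prep = "standard", target_depth = depths[["cultured_symbiont"]])
  df <- do.call(rbind, rows)
  DataFrame(df, row.names = df$sample_id)
}

.CONTRASTS <- c("host_response", "symbiont_intracellular",
                "symbiont_culture")

#' Simulate ground-truth expression, effects and bias parameters
#'
#' Plants, per gene: a baseline relative expression level (log-normal)
#' per condition; differential expression of known sign and magnitude for
#' three contrasts (host response to the symbiont, symbiont intracellular
#' vs capsule, symbiont capsule vs culture); a gene-wise NB dispersion
#' (log-normal scatter around `dispersion`); a log-linear GC-bias model
#' per library prep (counts suppressed above a GC breakpoint in the
#' low-input prep, flat in the standard prep); and a per-sample symbiont
#' depth fraction for symbiont reads inside host cells.
#'
#' @param catalog a [TranscriptCatalog-class].
#' @param design a sample sheet from [simulateDesign()].
#' @param fracDE fraction of eligible genes differentially expressed per
#'   contrast.
#' @param log2Effect absolute planted log2 fold change (sign random).
#' @param dispersion median NB dispersion; 0 gives Poisson counts.
#' @param dispersionSdLog log-sd of gene-wise dispersion scatter.
#' @param gcBias list per library prep: `breakpoint` and log-scale
#'   `slope` applied to GC above the breakpoint.
#' @param symbiontDepthFraction fraction of a host-plus-symbiont
#'   library's depth contributed per unit of symbiont expression
#'   (expression-dependent dropout arises from this depth deficit).
#' @param contaminantFraction contaminant share of wild library depth.
#' @param exprMeanLog,exprSdLog log-normal baseline expression parameters.
#' @param seed integer seed.
#' @return a [SimTruth-class].
#' @export
simulateTruth <- function(catalog, design, fracDE = 0.1, log2Effect = 2,
                          dispersion = 0.1, dispersionSdLog = 0.5,
                          gcBias = list(
                            low_input = c(breakpoint = 0.6, slope = -8),
                            standard = c(breakpoint = 0.6, slope = 0)),
                          symbiontDepthFraction = 0.05,
                          contaminantFraction = 0.005,
                          exprMeanLog = 3, exprSdLog = 1.5, seed = 1L) {
  stopifnot(is(catalog, "TranscriptCatalog"), fracDE >= 0, fracDE <= 1)
  n <- nrow(catalog)
  org <- catalog$organism
  conds <- .SAMPLE_CLASSES
  withStream(seed, "truth", "", {
    base <- stats::rlnorm(n, exprMeanLog, exprSdLog)
    de <- matrix(0L, n, 3, dimnames = list(catalog$transcript_id, .CONTRASTS))
    lfc <- matrix(0, n, 3, dimnames = dimnames(de))
    elig <- list(host_response = org == "host",
                 symbiont_intracellular = org == "symbiont",
                 symbiont_culture = org == "symbiont")
    for (k in .CONTRASTS) {
      idx <- which(elig[[k]])
      nde <- round(fracDE * length(idx))
      pick <- if (nde > 0) sample(idx, nde) else integer(0)
      sgn <- sample(c(-1L, 1L), length(pick), replace = TRUE)
      de[pick, k] <- sgn
      lfc[pick, k] <- sgn * log2Effect
    }
    phi <- if (dispersion > 0)
      dispersion * stats::rlnorm(n, 0, dispersionSdLog) else rep(0, n)
  })
  bm <- matrix(0, n, length(conds),
               dimnames = list(catalog$transcript_id, conds))
  # reference condition per organism: host_only (host), capsule (symbiont)
  bm[, "host_only"] <- ifelse(org == "host", base, 0)
  bm[, "capsule_symbiont"] <- ifelse(org == "symbiont", base, 0)
  bm[, "host_plus_symbiont"] <-
    ifelse(org == "host", base * 2^lfc[, "host_response"],
    ifelse(org == "symbiont", base * 2^lfc[, "symbiont_intracellular"], 0))
  bm[, "cultured_symbiont"] <-
    ifelse(org == "symbiont", base * 2^(-lfc[, "symbiont_culture"]), 0)
  # contaminants are present at low level in all wild conditions
  isCont <- grepl("^contaminant", org)
  bm[isCont, c("host_only", "host_plus_symbiont", "capsule_symbiont")] <-
    base[isCont]
  sdf <- rep(1, nrow(design))
  names(sdf) <- design$sample_id
  sdf[design$sample_class == "host_plus_symbiont"] <- symbiontDepthFraction
  new("SimTruth", baselineMean = bm, deIndicator = de, log2Effect = lfc,
      dispersion = phi, gcBias = gcBias,
      symbiontDepthFraction = sdf,
      contaminantFraction = contaminantFraction, seed = as.integer(seed))
}

.gcMultiplier <- function(gc, biasPar) {
  bp <- biasPar[["breakpoint"]]; sl <- biasPar[["slope"]]
  exp(sl * pmax(0, gc - bp))
}

# organisms sequenced in each sample class
.PRESENT <- list(
  host_only = c("host", "contaminant_fungus", "contaminant_mite"),
  host_plus_symbiont = c("host", "symbiont", "contaminant_fungus",
                         "contaminant_mite"),
  capsule_symbiont = c("symbiont", "contaminant_fungus",
                       "contaminant_mite"),
  cultured_symbiont = "symbiont")

#' Simulate a dual RNA-seq count matrix
#'
#' Counts are drawn gene-by-gene from a negative binomial whose mean is
#' `target_depth x relative expression x GC-bias multiplier`, with
#' symbiont genes in host-plus-symbiont samples additionally scaled by
#' that sample's symbiont depth fraction — the depth imbalance that
#' produces expression-dependent dropout of symbiont genes inside host
#' cells. Relative expression is the condition's baseline mean normalised
#' to sum to one within each organism's own compartment; contaminants
#' occupy a small fixed fraction of wild libraries.
#'
#' @param catalog a [TranscriptCatalog-class].
#' @param design a sample sheet from [simulateDesign()].
#' @param truth a [SimTruth-class] covering every catalog transcript.
#' @return a [DualSeqExperiment-class] with the truth in `metadata()`.
#' @export
simulateCounts <- function(catalog, design, truth) {
  stopifnot(is(catalog, "TranscriptCatalog"), is(truth, "SimTruth"))
  if (nrow(design) == 0) stop("design is empty")
  missing <- setdiff(catalog$transcript_id, rownames(truth@baselineMean))
  if (length(missing))
    stop("transcripts missing from truth: ", missing[1],
         if (length(missing) > 1) sprintf(" (+%d more)", length(missing) - 1))
  org <- catalog$organism
  gc <- catalog$gc_fraction
  ids <- catalog$transcript_id
  bm <- truth@baselineMean[ids, , drop = FALSE]
  phi <- truth@dispersion[match(ids, rownames(truth@baselineMean))]
  cnt <- matrix(0, nrow(catalog), nrow(design),
                dimnames = list(ids, design$sample_id))
  isCont <- grepl("^contaminant", org)
  for (s in seq_len(nrow(design))) {
    cls <- design$sample_class[s]
    sid <- design$sample_id[s]
    depth <- design$target_depth[s]
    bias <- .gcMultiplier(gc, truth@gcBias[[design$library_prep[s]]])
    w <- numeric(nrow(catalog))
    present <- .PRESENT[[cls]]
    for (o in c("host", "symbiont")) {
      if (!o %in% present) next
      m <- org == o
      tot <- sum(bm[m, cls])
      if (tot == 0) next
      fr <- if (o == "symbiont")
        truth@symbiontDepthFraction[[sid]] else 1
      w[m] <- bm[m, cls] / tot * fr
    }
    if (any(isCont & org %in% present)) {
      m <- isCont
      tot <- sum(bm[m, cls])
      if (tot > 0) w[m] <- bm[m, cls] / tot * truth@contaminantFraction
    }
    mu <- depth * w * bias
    cnt[, s] <- withStream(truth@seed, "counts", sid, {
      k <- numeric(length(mu))
      pois <- phi <= 0 | mu == 0
      k[pois] <- stats::rpois(sum(pois), mu[pois])
      if (any(!pois))
        k[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                   size = 1 / phi[!pois])
      k
    })
  }
  storage.mode(cnt) <- "integer"
  se <- SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = DataFrame(organism = org, length_bp = catalog$length_bp,
                        gc_fraction = gc, row.names = ids),
    colData = design)
  out <- new("DualSeqExperiment", se)
  metadata(out)$truth <- truth
  out
}

.ORG2GROUP <- c(host = "animal_or_vertebrate",
                symbiont = "plant_or_green_alga",
                contaminant_fungus = "fungal",
                contaminant_mite = "mite")

#' Simulate a BLAST-like homology hit table
#'
#' Each transcript receives, with probability `1 - assignmentErrorRate -
#' noHitRate`, a best-scoring hit whose taxon group matches its true
#' organism; with probability `assignmentErrorRate` a best hit to a wrong
#' group; and no hits otherwise. One or two lower-scoring decoy hits to
#' random groups accompany each best hit, so best-hit selection is
#' actually exercised.
#'
#' @param catalog a [TranscriptCatalog-class].
#' @param assignmentErrorRate probability the best hit's taxon group is
#'   wrong.
#' @param noHitRate probability a transcript has no hits at all.
#' @param seed integer seed.
#' @return a data.frame of hit records (BLAST outfmt-6 columns plus
#'   `taxon_group`).
#' @export
simulateHitTable <- function(catalog, assignmentErrorRate = 0.02,
                             noHitRate = 0.05, seed = 1L) {
  stopifnot(is(catalog, "TranscriptCatalog"))
  if (assignmentErrorRate < 0 || noHitRate < 0 ||
      assignmentErrorRate + noHitRate > 1)
    stop("assignmentErrorRate + noHitRate must be <= 1 (both >= 0)")
  n <- nrow(catalog)
  withStream(seed, "hits", "", {
    u <- stats::runif(n)
    fate <- ifelse(u < noHitRate, "none",
            ifelse(u < noHitRate + assignmentErrorRate, "wrong", "correct"))
    keep <- which(fate != "none")
    if (!length(keep)) {
      .emptyHitTable()
    } else {
    trueGrp <- .ORG2GROUP[catalog$organism[keep]]
    grp <- trueGrp
    wrong <- fate[keep] == "wrong"
    if (any(wrong))
      grp[wrong] <- vapply(trueGrp[wrong], function(g)
        sample(setdiff(.TAXON_GROUPS, g), 1), "")
    nDecoy <- sample(0:2, length(keep), replace = TRUE)
    bestScore <- stats::runif(length(keep), 150, 400)
    rows <- vector("list", length(keep))
    for (i in seq_along(keep)) {
      tx <- catalog$transcript_id[keep[i]]
      L <- catalog$length_bp[keep[i]]
      grps <- c(grp[i],
                sample(.TAXON_GROUPS, nDecoy[i], replace = TRUE))
      scores <- c(bestScore[i],
                  bestScore[i] - stats::runif(nDecoy[i], 5, 120))
      alen <- pmax(30L, as.integer(round(L * stats::runif(1 + nDecoy[i],
                                                          0.3, 0.95))))
      pid <- round(stats::runif(1 + nDecoy[i], 60, 99.5), 1)
      mism <- as.integer(round(alen * (100 - pid) / 100))
      rows[[i]] <- data.frame(
        qseqid = tx,
        sseqid = sprintf("%s|%s_%02d", toupper(substr(grps, 1, 4)), tx,
                         seq_along(grps)),
        pident = pid, length = alen, mismatch = mism,
        gapopen = 0L, qstart = 1L, qend = alen, sstart = 1L, send = alen,
        evalue = 10^(-scores / 10), bitscore = round(scores, 1),
        taxon_group = grps)
    }
    do.call(rbind, rows)
    }
  })
}

.emptyHitTable <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             taxon_group = character())
}
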