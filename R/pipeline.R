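#' @include AllClasses.R simulate.R partition.R depth_filters.R
#'   normalization.R de.R hssp.R io.R
NULL

.roundHalfUp <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Differential-expression proportion, as printed percent
#'
#' @param nDe number of differentially expressed genes.
#' @param nTested number of genes tested.
#' @return `100 * nDe / nTested`, rounded half-up to 2 decimals.
#' @export
#' @examples
#' deProportions(277, 6726)   # 4.12
#' deProportions(300, 46549)  # 0.64
deProportions <- function(nDe, nTested) {
  stopifnot(nDe >= 0)
  if (any(nTested <= 0)) stop("nTested must be > 0")
  if (any(nDe > nTested)) stop("nDe cannot exceed nTested")
  .roundHalfUp(100 * nDe / nTested, 2)
}

#' Ratio of two DE proportions
#'
#' @param nDeA,nTestedA,nDeB,nTestedB DE and tested counts of the two
#'   gene sets.
#' @return `(nDeA/nTestedA) / (nDeB/nTestedB)`, rounded half-up to 1
#'   decimal.
#' @export
#' @examples
#' deProportionRatio(277, 6726, 300, 46549)  # 6.4
deProportionRatio <- function(nDeA, nTestedA, nDeB, nTestedB) {
  if (any(c(nDeA, nTestedA, nDeB, nTestedB) <= 0))
    stop("all counts must be positive")
  .roundHalfUp((nDeA / nTestedA) / (nDeB / nTestedB), 1)
}

#' Convert a cross-sectional area fraction to a volume fraction
#'
#' Under isometric scaling a relative linear dimension r satisfies
#' r^2 = area fraction, so the volume fraction is r^3 =
#' (area fraction)^(3/2). Used to express, e.g., a reduction of starch
#' reserves measured by cross-sectional area on micrographs as a
#' reduction by volume.
#'
#' @param areaFraction area fraction in (0, 1].
#' @return the corresponding volume fraction.
#' @export
#' @examples
#' areaToVolumeFraction(0.56)  # ~0.42
areaToVolumeFraction <- function(areaFraction) {
  if (any(areaFraction <= 0 | areaFraction > 1))
    stop("areaFraction must lie in (0, 1]")
  areaFraction^(3 / 2)
}

.defaultConfig <- function() {
  list(seed = 1L,
       simulation = list(nHost = 4000, nSymbiont = 2000,
                         nContaminant = 100, fracDE = 0.1,
                         log2Effect = 2, dispersion = 0.1,
                         nPairs = 4, nCapsule = 3, nCultured = 0,
                         depths = c(host_only = 1e7,
                                    host_plus_symbiont = 1e7,
                                    capsule_symbiont = 3e7,
                                    cultured_symbiont = 3e7),
                         assignmentErrorRate = 0.02, noHitRate = 0.05,
                         symbiontDepthFraction = 0.05),
       inputs = NULL,
       window = 100, step = 1, runLength = 20, detectionTarget = 0.95,
       trimM = 0.30, trimA = 0.05, priorDf = 10, alpha = 0.05,
       annotationMinDist = 5,
       stages = list(partition = TRUE, filter = TRUE, normalize = TRUE,
                     de = TRUE, annotate = TRUE))
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to the package defaults; `simulation`
#' and `inputs` are mutually exclusive.
#'
#' @param path YAML file.
#' @return configuration list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .defaultConfig()
  if (!is.null(user$inputs)) cfg$simulation <- NULL
  for (nm in names(user)) {
    if (nm %in% c("simulation", "stages") && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  if (!is.null(cfg$simulation) && !is.null(cfg$simulation$depths))
    cfg$simulation$depths <- unlist(cfg$simulation$depths)
  cfg
}

.validateConfig <- function(config) {
  hasSim <- !is.null(config$simulation)
  hasInp <- !is.null(config$inputs)
  if (hasSim == hasInp)
    stop("exactly one of 'simulation' or 'inputs' must be provided")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  invisible(config)
}

.loadInputs <- function(config) {
  if (!is.null(config$simulation)) {
    p <- config$simulation
    catalog <- simulateCatalog(nHost = p$nHost, nSymbiont = p$nSymbiont,
                               nContaminant = p$nContaminant,
                               seed = config$seed)
    design <- simulateDesign(nPairs = p$nPairs, nCapsule = p$nCapsule,
                             nCultured = p$nCultured, depths = p$depths)
    truth <- simulateTruth(catalog, design, fracDE = p$fracDE,
                           log2Effect = p$log2Effect,
                           dispersion = p$dispersion,
                           symbiontDepthFraction = p$symbiontDepthFraction,
                           seed = config$seed)
    se <- simulateCounts(catalog, design, truth)
    hits <- simulateHitTable(catalog,
                             assignmentErrorRate = p$assignmentErrorRate,
                             noHitRate = p$noHitRate, seed = config$seed)
    list(se = se, hits = hits)
  } else {
    p <- config$inputs
    cnt <- readCountsTSV(p$counts)
    design <- readDesignTSV(p$design)
    meta <- readCatalogMeta(p$catalogMeta)
    m <- match(rownames(cnt), meta$transcript_id)
    se <- new("DualSeqExperiment", SummarizedExperiment(
      assays = list(counts = cnt[, rownames(design), drop = FALSE]),
      rowData = DataFrame(organism = meta$organism[m],
                          length_bp = meta$length_bp[m],
                          gc_fraction = meta$gc_fraction[m],
                          row.names = rownames(cnt)),
      colData = design))
    hits <- readHitTable(p$hits, p$hitMap)
    list(se = se, hits = hits)
  }
}

#' Run the dual RNA-seq pipeline end-to-end
#'
#' Executes (optionally) simulation, then catalog partitioning, the
#' depth-driven threshold filters, TMM/GC normalization, paired NB GLM
#' differential expression for each available contrast, and HSSP-based
#' annotation filtering, recording an auditable per-stage count ledger.
#' Fully deterministic given `config$seed`. Any stage failure aborts
#' with the stage name.
#'
#' @param config configuration list (see [readPipelineConfig()] and the
#'   package vignette) or path to a YAML file.
#' @return a [RunReport-class]; the intermediate objects (experiment,
#'   assignments, thresholds, DE tables) are attached as attribute
#'   `artifacts`.
#' @export
runPipeline <- function(config = .defaultConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  .validateConfig(config)
  stageTry <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  stages <- data.frame(stage = character(), input = integer(),
                       removed = integer(), retained = integer())
  addStage <- function(stage, input, retained) {
    stages <<- rbind(stages, data.frame(
      stage = stage, input = as.integer(input),
      removed = as.integer(input - retained),
      retained = as.integer(retained)))
  }
  dat <- stageTry("load", .loadInputs(config))
  se <- dat$se
  hits <- dat$hits
  nAll <- nrow(se)
  addStage("input_transcripts", nAll, nAll)
  artifacts <- list(experiment = se, hits = hits)
  thresholds <- NULL
  deTally <- NULL
  summaries <- list()
  on <- function(s) isTRUE(config$stages[[s]])

  hostGenes <- symGenes <- character()
  if (on("partition")) {
    asg <- stageTry("partition",
                    classifyByBestHit(hits, transcriptIds = rownames(se)))
    drop1 <- sum(asg$label %in% c("contaminant", "ambiguous"))
    addStage("homology_partition", nAll, nAll - drop1)
    hostGenes <- asg$transcript_id[asg$label == "host"]
    symGenes <- asg$transcript_id[asg$label == "symbiont"]
    artifacts$assignments <- asg
  }
  if (on("filter")) {
    thresholds <- stageTry("thresholds",
      estimateThresholds(se, hostGenes, symGenes,
                         window = config$window, step = config$step,
                         runLength = config$runLength,
                         detectionTarget = config$detectionTarget))
    artifacts$thresholds <- thresholds
    if (on("partition")) {
      asg <- artifacts$assignments
      unk <- asg$transcript_id[asg$label == "unknown"]
      if (length(unk)) {
        resc <- stageTry("rescue", rescueUnknowns(unk, se, thresholds))
        m <- match(resc$transcript_id, asg$transcript_id)
        asg$label[m] <- resc$label
        asg$evidence[m] <- resc$evidence
        addStage("expression_rescue", length(unk),
                 sum(resc$label != "unknown"))
        artifacts$assignments <- asg
        hostGenes <- asg$transcript_id[asg$label == "host"]
        symGenes <- asg$transcript_id[asg$label == "symbiont"]
      }
      symSet <- stageTry("symbiont_gene_set",
        buildSymbiontGeneSet(se, asg, thresholds))
      addStage("symbiont_gene_set", length(symGenes), length(symSet))
      # absence-call filter on the symbiont set
      cls <- sampleClass(se)
      if (any(cls == "host_plus_symbiont") && length(symSet)) {
        fk <- fpkm(se)
        ref <- rowMeans(fk[symSet, cls == "capsule_symbiont",
                           drop = FALSE])
        det <- rowSums(counts(se)[symSet, cls == "host_plus_symbiont",
                                  drop = FALSE] > 0) ==
          sum(cls == "host_plus_symbiont")
        thr <- thresholds@absenceThreshold
        if (is.finite(thr) && !is.na(thr)) {
          kept <- applyAbsenceFilter(symSet, ref, det, thr)
          addStage("absence_filter", length(symSet), length(kept))
          symSet <- kept
        }
      }
      artifacts$symbiontGeneSet <- symSet
      symGenes <- symSet
    }
  }
  norm <- NULL
  if (on("normalize")) {
    norm <- stageTry("normalize", tmmFactors(counts(se),
                                             trimM = config$trimM,
                                             trimA = config$trimA))
    artifacts$norm <- norm
  }
  if (on("de")) {
    cls <- sampleClass(se)
    deTabs <- list()
    runContrast <- function(name, genes, classA, classB, paired) {
      sel <- cls %in% c(classA, classB)
      genes <- intersect(genes, rownames(se))
      if (length(genes) < 2 || sum(cls == classA) < 2 ||
          sum(cls == classB) < 2) return(NULL)
      cnt <- counts(se)[genes, sel, drop = FALSE]
      cond <- factor(cls[sel], levels = c(classA, classB))
      pr <- if (paired) pairId(se)[sel] else NULL
      gcOff <- NULL
      if (classB == "cultured_symbiont" || classA == "cultured_symbiont") {
        mod <- fitGCOffsets(cnt, gc = gcFraction(se)[match(genes,
                                                           rownames(se))])
        gcOff <- offsetMatrix(mod, gcFraction(se)[match(genes,
                                                        rownames(se))])
        artifacts$gcOffsets <<- mod
      }
      stageTry(paste0("de_", name),
               runDE(cnt, cond, pair = pr, gcOffsets = gcOff,
                     priorDf = config$priorDf, alpha = config$alpha))
    }
    deTabs$host_response <- runContrast("host_response", hostGenes,
                                        "host_only",
                                        "host_plus_symbiont", TRUE)
    deTabs$symbiont_intracellular <-
      runContrast("symbiont_intracellular", symGenes,
                  "capsule_symbiont", "host_plus_symbiont", FALSE)
    if (any(cls == "cultured_symbiont"))
      deTabs$symbiont_culture <-
        runContrast("symbiont_culture", symGenes, "cultured_symbiont",
                    "capsule_symbiont", FALSE)
    deTabs <- Filter(Negate(is.null), deTabs)
    artifacts$de <- deTabs
    if (length(deTabs)) {
      deTally <- do.call(rbind, lapply(names(deTabs), function(nm) {
        s <- attr(deTabs[[nm]], "summary")
        data.frame(contrast = nm, tested = s$tested, total = s$total,
                   up = s$up, down = s$down,
                   percent_de = deProportions(s$total, s$tested))
      }))
      rownames(deTally) <- NULL
      if (all(c("host_response", "symbiont_intracellular") %in%
                deTally$contrast)) {
        a <- deTally[deTally$contrast == "symbiont_intracellular", ]
        b <- deTally[deTally$contrast == "host_response", ]
        if (a$total > 0 && b$total > 0)
          summaries$symbiont_vs_host_de_ratio <-
            deProportionRatio(a$total, a$tested, b$total, b$tested)
      }
    }
  }
  if (on("annotate") && nrow(hits)) {
    ann <- stageTry("annotate",
      filterAnnotations(hits, minDist = config$annotationMinDist))
    addStage("annotation_filter", length(unique(hits$qseqid)),
             nrow(ann$annotations))
    artifacts$annotations <- ann$annotations
  }
  rep <- new("RunReport", stages = stages, thresholds = thresholds,
             deTally = deTally, summaries = summaries,
             config = config, seed = as.integer(config$seed))
  attr(rep, "artifacts") <- artifacts
  rep
}
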