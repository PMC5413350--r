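#' @include AllClasses.R
NULL

#' Accessors for dual RNA-seq containers
#'
#' `organism()`, `gcFraction()` and `lengthBp()` extract per-transcript
#' annotation; `sampleClass()`, `pairId()`, `libraryPrep()` and
#' `targetDepth()` extract per-sample annotation; `counts()` extracts the
#' count assay; `simTruth()` extracts the simulation ground truth stored
#' with a simulated experiment (or `NULL`); `lowerLimits()` and
#' `absenceThreshold()` extract learned thresholds.
#'
#' @param x a [DualSeqExperiment-class], [TranscriptCatalog-class] or
#'   [ThresholdSet-class] as appropriate.
#' @return The annotation vector, matrix or threshold value.
#' @name accessors
#' @aliases counts organism gcFraction lengthBp sampleClass pairId
#'   libraryPrep targetDepth simTruth lowerLimits absenceThreshold
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))
#' @rdname accessors
#' @export
setGeneric("gcFraction", function(x) standardGeneric("gcFraction"))
#' @rdname accessors
#' @export
setGeneric("lengthBp", function(x) standardGeneric("lengthBp"))
#' @rdname accessors
#' @export
setGeneric("sampleClass", function(x) standardGeneric("sampleClass"))
#' @rdname accessors
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))
#' @rdname accessors
#' @export
setGeneric("libraryPrep", function(x) standardGeneric("libraryPrep"))
#' @rdname accessors
#' @export
setGeneric("targetDepth", function(x) standardGeneric("targetDepth"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setGeneric("lowerLimits", function(x) standardGeneric("lowerLimits"))
#' @rdname accessors
#' @export
setGeneric("absenceThreshold", function(x) standardGeneric("absenceThreshold"))

#' Fragments per kilobase per million mapped reads
#'
#' @param x counts (matrix or [DualSeqExperiment-class]).
#' @param ... passed to methods.
#' @return numeric matrix of FPKM values with the shape of the counts.
#' @export
setGeneric("fpkm", function(x, ...) standardGeneric("fpkm"))

#' Counts per million (effective library sizes)
#'
#' @param x counts (matrix or [DualSeqExperiment-class]).
#' @param ... passed to methods.
#' @return numeric matrix of CPM values.
#' @export
setGeneric("cpm", function(x, ...) standardGeneric("cpm"))

setMethod("counts", "DualSeqExperiment",
          function(x) assay(x, "counts"))
setMethod("organism", "DualSeqExperiment",
          function(x) rowData(x)$organism)
setMethod("organism", "TranscriptCatalog", function(x) x$organism)
setMethod("gcFraction", "DualSeqExperiment",
          function(x) rowData(x)$gc_fraction)
setMethod("gcFraction", "TranscriptCatalog", function(x) x$gc_fraction)
setMethod("lengthBp", "DualSeqExperiment",
          function(x) rowData(x)$length_bp)
setMethod("lengthBp", "TranscriptCatalog", function(x) x$length_bp)
setMethod("sampleClass", "DualSeqExperiment",
          function(x) colData(x)$sample_class)
setMethod("pairId", "DualSeqExperiment", function(x) colData(x)$pair_id)
setMethod("libraryPrep", "DualSeqExperiment",
          function(x) colData(x)$library_prep)
setMethod("targetDepth", "DualSeqExperiment",
          function(x) colData(x)$target_depth)
setMethod("simTruth", "DualSeqExperiment",
          function(x) metadata(x)$truth)
setMethod("lowerLimits", "ThresholdSet", function(x) x@lowerLimits)
setMethod("absenceThreshold", "ThresholdSet",
          function(x) x@absenceThreshold)

setMethod("show", "DualSeqExperiment", function(object) {
  callNextMethod()
  cat("sample classes:",
      paste(sprintf("%s(%d)", names(table(sampleClass(object))),
                    table(sampleClass(object))), collapse = " "), "\n")
  if (!is.null(simTruth(object)))
    cat("simulated: ground truth available via simTruth()\n")
})

setMethod("show", "ThresholdSet", function(object) {
  cat("ThresholdSet\n  lower limits (FPKM):\n")
  for (nm in names(object@lowerLimits))
    cat(sprintf("    %-22s %s\n", nm,
                format(object@lowerLimits[[nm]], digits = 4)))
  cat(sprintf("  absence threshold (FPKM): %s (detection target %.2f)\n",
              format(object@absenceThreshold, digits = 4),
              object@detectionTarget))
  cat(sprintf("  window: %d genes\n", as.integer(object@window)))
})

setMethod("show", "DispersionEstimates", function(object) {
  cat(sprintf(
    "DispersionEstimates: common %.4g; tagwise over %d genes (range %.4g-%.4g); prior df %g\n",
    object@common, length(object@tagwise), min(object@tagwise),
    max(object@tagwise), object@priorDf))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d genes, %d conditions, contrasts: %s; seed %d\n",
    nrow(object@baselineMean), ncol(object@baselineMean),
    paste(colnames(object@deIndicator), collapse = ", "), object@seed))
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport (seed", object@seed, ")\n")
  cat("Stages (input / removed / retained):\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-28s %8d %8d %8d\n", st$stage[i], st$input[i],
                st$removed[i], st$retained[i]))
  if (!is.null(object@deTally) && nrow(object@deTally)) {
    cat("Differential expression (tested / DE / up / down / %DE):\n")
    de <- object@deTally
    for (i in seq_len(nrow(de)))
      cat(sprintf("  %-28s %8d %6d %5d %5d %7.2f\n", de$contrast[i],
                  de$tested[i], de$total[i], de$up[i], de$down[i],
                  de$percent_de[i]))
  }
  if (length(object@summaries)) {
    cat("Summaries:\n")
    for (nm in names(object@summaries)) {
      v <- object@summaries[[nm]]
      if (is.numeric(v) && length(v) == 1L)
        cat(sprintf("  %-34s %s\n", nm, format(v)))
    }
  }
  invisible(object)
})
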