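#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData rowData<- colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

.ORGANISMS <- c("host", "symbiont", "contaminant_fungus", "contaminant_mite")
.SAMPLE_CLASSES <- c("host_only", "host_plus_symbiont", "capsule_symbiont",
                     "cultured_symbiont")
.TAXON_GROUPS <- c("plant_or_green_alga", "animal_or_vertebrate", "fungal",
                   "mite", "other")
.LIBRARY_PREPS <- c("low_input", "standard")

#' TranscriptCatalog: per-transcript organism, length and GC content
#'
#' A `DataFrame` subclass holding one row per transcript of a (possibly
#' mixed, two-organism) transcript catalog, with the columns
#' `transcript_id`, `organism` (one of `"host"`, `"symbiont"`,
#' `"contaminant_fungus"`, `"contaminant_mite"`), `length_bp` and
#' `gc_fraction`.
#'
#' @seealso [simulateCatalog()], [writeCatalogFasta()]
#' @export
setClass("TranscriptCatalog", contains = "DFrame")

setValidity("TranscriptCatalog", function(object) {
  req <- c("transcript_id", "organism", "length_bp", "gc_fraction")
  miss <- setdiff(req, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$transcript_id))
    return("transcript_ids must be unique")
  if (!all(object$organism %in% .ORGANISMS))
    return("unknown organism label")
  if (any(object$length_bp < 100))
    return("length_bp must be >= 100")
  if (any(object$gc_fraction < 0 | object$gc_fraction > 1))
    return("gc_fraction must lie in [0, 1]")
  TRUE
})

#' SimTruth: ground truth behind a simulated dual RNA-seq experiment
#'
#' Holds everything needed to score downstream inference against the
#' simulation: per-gene baseline mean expression per condition (on a
#' relative, transcripts-per-million-like scale), differential-expression
#' indicators and log2 effect sizes per contrast, per-gene negative
#' binomial dispersions, the GC-bias model per library preparation, the
#' per-sample symbiont depth fraction, and the master seed.
#'
#' @slot baselineMean numeric matrix, genes x conditions.
#' @slot deIndicator integer matrix in {-1, 0, +1}, genes x contrasts.
#' @slot log2Effect numeric matrix, genes x contrasts; nonzero exactly
#'   where `deIndicator` is nonzero.
#' @slot dispersion per-gene NB dispersion (>= 0).
#' @slot gcBias named list per library prep with elements `breakpoint`
#'   and `slope` (log-scale count multiplier per unit GC above the
#'   breakpoint).
#' @slot symbiontDepthFraction named numeric per sample, in (0, 1].
#' @slot contaminantFraction fraction of library depth from contaminants.
#' @slot seed master integer seed.
#' @export
setClass("SimTruth",
  slots = c(baselineMean = "matrix", deIndicator = "matrix",
            log2Effect = "matrix", dispersion = "numeric",
            gcBias = "list", symbiontDepthFraction = "numeric",
            contaminantFraction = "numeric", seed = "integer"))

setValidity("SimTruth", function(object) {
  if (any(object@baselineMean < 0)) return("baseline means must be >= 0")
  if (any(object@dispersion < 0)) return("dispersions must be >= 0")
  if (!identical(dim(object@deIndicator), dim(object@log2Effect)))
    return("deIndicator and log2Effect must have identical shape")
  bad <- (object@deIndicator != 0) != (abs(object@log2Effect) > 0)
  if (any(bad))
    return("|log2Effect| > 0 required exactly where deIndicator != 0")
  if (any(object@symbiontDepthFraction <= 0 |
          object@symbiontDepthFraction > 1))
    return("symbiontDepthFraction must lie in (0, 1]")
  TRUE
})

#' DualSeqExperiment: counts plus transcript and sample annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass for dual
#' RNA-seq count data. The `counts` assay holds genes x samples integer
#' counts; `rowData` carries `organism`, `length_bp` and `gc_fraction`;
#' `colData` carries `sample_class` (one of `"host_only"`,
#' `"host_plus_symbiont"`, `"capsule_symbiont"`, `"cultured_symbiont"`),
#' `pair_id` (blocking factor, `NA` when unpaired), `library_prep`
#' (`"low_input"` or `"standard"`) and `target_depth`. Simulated objects
#' additionally carry their [SimTruth-class] in `metadata(x)$truth`.
#'
#' @export
setClass("DualSeqExperiment", contains = "SummarizedExperiment")

setValidity("DualSeqExperiment", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("a 'counts' assay is required")
  rd <- rowData(object)
  miss <- setdiff(c("organism", "length_bp", "gc_fraction"), colnames(rd))
  if (length(miss))
    return(paste("rowData missing:", paste(miss, collapse = ", ")))
  cd <- colData(object)
  miss <- setdiff(c("sample_class", "pair_id", "library_prep",
                    "target_depth"), colnames(cd))
  if (length(miss))
    return(paste("colData missing:", paste(miss, collapse = ", ")))
  if (!all(cd$sample_class %in% .SAMPLE_CLASSES))
    return("unknown sample_class")
  if (!all(cd$library_prep %in% .LIBRARY_PREPS))
    return("unknown library_prep")
  cnt <- assay(object, "counts")
  if (any(cnt < 0)) return("counts must be non-negative")
  # paired host samples must pair one host_only with one host_plus_symbiont
  hp <- cd[cd$sample_class == "host_plus_symbiont", , drop = FALSE]
  for (p in unique(stats::na.omit(hp$pair_id))) {
    mate <- cd$sample_class[!is.na(cd$pair_id) & cd$pair_id == p]
    if (sum(mate == "host_only") != 1L ||
        sum(mate == "host_plus_symbiont") != 1L)
      return(sprintf(
        "pair '%s' must contain exactly one host_only and one host_plus_symbiont sample", p))
  }
  TRUE
})

#' ThresholdSet: data-derived expression thresholds
#'
#' Lower-limit FPKM thresholds per condition (the expression level where
#' between-condition correlation of window medians sets in) and the
#' detection-proportion absence-call threshold for a shallow condition,
#' together with the window curves that justify them.
#'
#' @slot lowerLimits named numeric, FPKM lower limit per condition
#'   (`+Inf` with a note in `curves` when onset detection failed).
#' @slot absenceThreshold FPKM in the deep condition above which an
#'   absence call in the shallow condition is treated as biological;
#'   `NA_real_` when not estimated, 0 when no filtering is needed.
#' @slot detectionTarget required detection proportion (default 0.95).
#' @slot window sliding window width in genes (default 100).
#' @slot curves named list of window-curve data frames (diagnostics).
#' @export
setClass("ThresholdSet",
  slots = c(lowerLimits = "numeric", absenceThreshold = "numeric",
            detectionTarget = "numeric", window = "numeric",
            curves = "list"))

setValidity("ThresholdSet", function(object) {
  if (any(object@lowerLimits < 0, na.rm = TRUE))
    return("lower limits must be >= 0")
  if (length(object@absenceThreshold) != 1L)
    return("absenceThreshold must be a single value")
  if (!is.na(object@absenceThreshold) && object@absenceThreshold < 0)
    return("absenceThreshold must be >= 0")
  if (object@detectionTarget <= 0 || object@detectionTarget > 1)
    return("detectionTarget must lie in (0, 1]")
  TRUE
})

#' GCOffsetModel: quantile-bin GC (and length) offsets
#'
#' Additive log-scale per-sample offsets over GC-content bins (decile
#' boundaries by default), used to remove library-prep-dependent GC bias
#' before cross-prep differential expression. Offsets are zero-sum per
#' sample when weighted by the number of genes per bin, so applying them
#' leaves overall per-sample totals unchanged.
#'
#' @slot gcBreaks numeric bin boundaries on GC fraction.
#' @slot gcOffsets bins x samples matrix of natural-log offsets.
#' @slot gcBinCounts genes per GC bin.
#' @slot lengthBreaks,lengthOffsets,lengthBinCounts optional analogous
#'   length-bin model (`NULL`/empty when not fitted).
#' @export
setClass("GCOffsetModel",
  slots = c(gcBreaks = "numeric", gcOffsets = "matrix",
            gcBinCounts = "numeric", lengthBreaks = "numericOrNULL",
            lengthOffsets = "ANY", lengthBinCounts = "numericOrNULL"))

setValidity("GCOffsetModel", function(object) {
  if (nrow(object@gcOffsets) != length(object@gcBinCounts))
    return("one offset row per GC bin required")
  ws <- colSums(object@gcOffsets * object@gcBinCounts)
  if (any(abs(ws) > 1e-6 * max(1, sum(object@gcBinCounts))))
    return("per-sample offsets must be zero-sum weighted by bin counts")
  TRUE
})

#' DispersionEstimates: common and tagwise NB dispersions
#'
#' @slot common common dispersion maximising the summed Cox-Reid adjusted
#'   profile likelihood.
#' @slot tagwise per-gene dispersions shrunk toward the common value.
#' @slot priorDf prior degrees of freedom controlling shrinkage; tagwise
#'   values approach the common dispersion as `priorDf` grows.
#' @export
setClass("DispersionEstimates",
  slots = c(common = "numeric", tagwise = "numeric", priorDf = "numeric"))

setValidity("DispersionEstimates", function(object) {
  if (object@common < 0) return("common dispersion must be >= 0")
  if (any(object@tagwise < 0)) return("tagwise dispersions must be >= 0")
  if (object@priorDf <= 0) return("priorDf must be > 0")
  TRUE
})

#' RunReport: auditable per-stage account of a pipeline run
#'
#' @slot stages data.frame with columns `stage`, `input`, `removed`,
#'   `retained`; `input == removed + retained` at every stage.
#' @slot thresholds the learned [ThresholdSet-class] (or `NULL`).
#' @slot deTally data.frame per contrast: `contrast`, `tested`, `total`,
#'   `up`, `down`, `percent_de` (with `up + down == total`).
#' @slot summaries list of derived summary quantities.
#' @slot config the configuration the run used.
#' @slot seed integer seed of the run.
#' @export
setClass("RunReport",
  slots = c(stages = "data.frame", thresholds = "ANY",
            deTally = "dfOrNULL", summaries = "list", config = "list",
            seed = "integer"))

setValidity("RunReport", function(object) {
  st <- object@stages
  if (nrow(st) &&
      !all(st$input == st$removed + st$retained))
    return("stage conservation violated: input != removed + retained")
  de <- object@deTally
  if (!is.null(de) && nrow(de) && !all(de$total == de$up + de$down))
    return("DE tally violated: total != up + down")
  TRUE
})
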