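#' @include AllClasses.R rng.R
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @importFrom utils read.delim write.table
NULL

#' Write a transcript catalog as FASTA plus metadata
#'
#' Emits synthetic sequences of each transcript's specified length and
#' GC fraction (bases drawn i.i.d. with P(G or C) = `gc_fraction`; no
#' claim of sequence-content realism beyond length and GC), plus a
#' tab-separated metadata file (`transcript_id`, `organism`,
#' `length_bp`, `gc_fraction`).
#'
#' @param catalog a [TranscriptCatalog-class].
#' @param fastaPath,metaPath output paths.
#' @param seed seed for the base draws.
#' @return invisibly, the FASTA path.
#' @export
writeCatalogFasta <- function(catalog, fastaPath, metaPath = NULL,
                              seed = 1L) {
  stopifnot(is(catalog, "TranscriptCatalog"))
  seqs <- withStream(seed, "fasta", "", {
    vapply(seq_len(nrow(catalog)), function(i) {
      gc <- catalog$gc_fraction[i]
      paste(sample(c("G", "C", "A", "T"), catalog$length_bp[i],
                   replace = TRUE,
                   prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
            collapse = "")
    }, "")
  })
  x <- DNAStringSet(seqs)
  names(x) <- catalog$transcript_id
  writeXStringSet(x, fastaPath)
  if (!is.null(metaPath))
    write.table(as.data.frame(catalog), metaPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}

#' Read a transcript catalog metadata file
#'
#' @param metaPath tab-separated file with columns `transcript_id`,
#'   `organism`, `length_bp`, `gc_fraction`.
#' @return a [TranscriptCatalog-class].
#' @export
readCatalogMeta <- function(metaPath) {
  df <- read.delim(metaPath, stringsAsFactors = FALSE)
  new("TranscriptCatalog",
      DataFrame(df, row.names = df$transcript_id))
}

#' Derive a transcript catalog from a FASTA file
#'
#' Computes `length_bp` and `gc_fraction` from the sequences; the
#' organism column is taken from `organisms` (named by transcript id)
#' when provided, else left as `"host"` placeholders to be overwritten
#' by classification.
#'
#' @param fastaPath FASTA file of transcripts.
#' @param organisms optional named organism labels.
#' @return a [TranscriptCatalog-class].
#' @export
catalogFromFasta <- function(fastaPath, organisms = NULL) {
  x <- Biostrings::readDNAStringSet(fastaPath)
  ids <- sub("\\s.*$", "", names(x))
  freq <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  gc <- (freq[, "G"] + freq[, "C"]) / rowSums(freq[, c("A", "C", "G", "T")])
  org <- if (is.null(organisms)) rep("host", length(x))
         else unname(organisms[ids])
  new("TranscriptCatalog",
      DataFrame(transcript_id = ids, organism = org,
                length_bp = Biostrings::width(x), gc_fraction = gc,
                row.names = ids))
}

#' Read and write counts, designs, hit tables and results
#'
#' Tab-separated interchange used by every stage: counts as genes x
#' samples with a header row and gene ids in the first column; the
#' sample sheet with one row per sample; hit tables in BLAST tabular
#' outfmt-6 column order plus a two-column `subject -> taxon_group` map.
#'
#' @param x object to write.
#' @param path,mapPath file path(s).
#' @return the read object, or (writers) the path invisibly.
#' @name io
NULL

#' @rdname io
#' @export
writeCountsTSV <- function(x, path) {
  if (is(x, "DualSeqExperiment")) x <- counts(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readCountsTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname io
#' @export
writeDesignTSV <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readDesignTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$pair_id[df$pair_id %in% c("", "NA")] <- NA_character_
  DataFrame(df, row.names = df$sample_id)
}

.OUTFMT6 <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send", "evalue",
              "bitscore")

#' @rdname io
#' @export
writeHitTable <- function(x, path, mapPath = NULL) {
  write.table(x[, .OUTFMT6], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(mapPath) && "taxon_group" %in% colnames(x)) {
    map <- unique(x[, c("sseqid", "taxon_group")])
    write.table(map, mapPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname io
#' @export
readHitTable <- function(path, mapPath = NULL) {
  hits <- read.delim(path, header = FALSE, col.names = .OUTFMT6,
                     stringsAsFactors = FALSE)
  if (!is.null(mapPath)) {
    map <- read.delim(mapPath, header = FALSE,
                      col.names = c("sseqid", "taxon_group"),
                      stringsAsFactors = FALSE)
    hits$taxon_group <- map$taxon_group[match(hits$sseqid, map$sseqid)]
    if (anyNA(hits$taxon_group))
      stop("subjects missing from the taxon group map")
  }
  hits
}

#' @rdname io
#' @export
writeThresholdsTSV <- function(x, path) {
  stopifnot(is(x, "ThresholdSet"))
  df <- data.frame(
    quantity = c(paste0("lower_limit.", names(x@lowerLimits)),
                 "absence_threshold", "detection_target", "window"),
    value = c(unname(x@lowerLimits), x@absenceThreshold,
              x@detectionTarget, x@window))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
writeAssignmentsTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
writeDETSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
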