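#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames start end strand width mcols
#'   mcols<- findOverlaps
#' @importFrom IRanges IRanges
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Probe and pseudogene annotation for base-matrix construction
#'
#' Holds the two ordered annotation tables that define the rows and columns
#' of a base matrix: extended gene regions ("pseudogenes") and array probes.
#' Order is significant -- it fixes the gene (row) and probe (column) indices
#' of every matrix built from the object.
#'
#' @slot pseudogenes A [GenomicRanges::GRanges] of extended gene regions with
#'   metadata columns `symbol` (unique HGNC-style gene name), `gene_start`,
#'   `gene_end` (the unextended source interval) and `probe_count` (number of
#'   member probes, `NA` until a base matrix has been built).
#' @slot probes A [GenomicRanges::GRanges] of probe intervals, named by
#'   probe identifier (unique).
#'
#' @examples
#' genes <- data.frame(symbol = "GENE1", chrom = "chr1",
#'                     start = 500000, end = 510000, strand = "+")
#' gf <- tempfile(fileext = ".tsv")
#' write.table(genes, gf, sep = "\t", quote = FALSE, row.names = FALSE)
#' g <- readGeneAnnotation(gf)
#' ann <- CnaAnnotation(extendGenes(g),
#'                      GRanges("chr1", IRanges(400000, width = 60),
#'                              probe_id = "P1"))
#' ann
#' @export
setClass("CnaAnnotation",
  slots = c(pseudogenes = "GRanges", probes = "GRanges"))

setValidity("CnaAnnotation", function(object) {
  msg <- character()
  pg <- object@pseudogenes
  pr <- object@probes
  if (!"symbol" %in% names(mcols(pg)))
    msg <- c(msg, "pseudogenes must carry a 'symbol' metadata column")
  else if (anyDuplicated(mcols(pg)$symbol))
    msg <- c(msg, "pseudogene symbols must be unique (run deduplicateGenes)")
  if (length(pr) > 0 && is.null(names(pr)))
    msg <- c(msg, "probes must be named by probe id")
  if (!is.null(names(pr)) && anyDuplicated(names(pr)))
    msg <- c(msg, "probe ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Sparse genes-by-probes base matrix
#'
#' The base matrix C maps probe-level measurements to gene level. Under the
#' `"binary"` scheme every member probe of a pseudogene contributes weight 1
#' (gene value = sum of member probes); under the `"averaged"` scheme each of
#' the k member probes contributes 1/k (gene value = mean of member probes).
#' Rows are genes, columns are probes; genes whose extended region captures
#' no probe have an all-zero row and `probeCounts()` of 0.
#'
#' @slot weights Sparse non-negative weight matrix (`Matrix::dgCMatrix`),
#'   dimnames = list(gene symbols, probe ids).
#' @slot scheme `"binary"` or `"averaged"`.
#' @slot probeCounts Integer vector, member-probe count k per gene.
#' @slot probeWidths Integer vector, base-pair length per probe (used for
#'   probe-coverage summaries).
#' @export
setClass("BaseMatrix",
  slots = c(weights = "dgCMatrix", scheme = "character",
            probeCounts = "integer", probeWidths = "integer"))

setValidity("BaseMatrix", function(object) {
  msg <- character()
  w <- object@weights
  if (!object@scheme %in% c("binary", "averaged"))
    msg <- c(msg, "scheme must be 'binary' or 'averaged'")
  if (length(object@probeCounts) != nrow(w))
    msg <- c(msg, "probeCounts length must equal number of genes")
  if (length(object@probeWidths) != ncol(w))
    msg <- c(msg, "probeWidths length must equal number of probes")
  if (any(w@x < 0))
    msg <- c(msg, "weights must be non-negative")
  if (object@scheme == "binary" && length(w@x) && any(w@x != 1))
    msg <- c(msg, "binary scheme: every stored weight must equal 1")
  if (object@scheme == "averaged" && nrow(w)) {
    rs <- Matrix::rowSums(w)
    nz <- Matrix::rowSums(w != 0) > 0
    if (any(abs(rs[nz] - 1) > 1e-9))
      msg <- c(msg, "averaged scheme: nonzero rows must sum to 1 (1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Gene-level copy number alteration (CNAR) experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the genes-by-samples
#' CNAR matrix (assay `"cnar"`, log2-ratio scale) produced by
#' [generateCnar()]. Row metadata records the gene symbol and member-probe
#' count; the `scheme` slot records which base-matrix weighting produced the
#' values. A CNAR value is `NA` iff the gene had no member probe or all its
#' member probes were missing for that sample.
#'
#' @slot scheme `"binary"` or `"averaged"` (provenance of the values).
#' @export
setClass("CnarExperiment",
  contains = "SummarizedExperiment",
  slots = c(scheme = "character"))

setValidity("CnarExperiment", function(object) {
  if (!object@scheme %in% c("binary", "averaged"))
    return("scheme must be 'binary' or 'averaged'")
  if (!"cnar" %in% SummarizedExperiment::assayNames(object))
    return("assay 'cnar' is required")
  TRUE
})

#' Leave-one-out cross-validation result
#'
#' Per-fold bookkeeping and aggregate accuracies of [loocvClassify()]. Each
#' of the n folds holds out one sample; gene ranking and classifier training
#' use only the remaining n-1 samples.
#'
#' @slot folds `DataFrame` with one row per fold: `sample`, `true` class and
#'   the predicted class at the selected feature count `bestM`.
#' @slot predictions Character matrix, folds x feature counts: the held-out
#'   prediction at every candidate m.
#' @slot features List of character vectors: the training-fold gene ranking
#'   (top max(mGrid) symbols) used for that fold's feature selection.
#' @slot mGrid Integer vector of candidate feature counts.
#' @slot accuracy Named numeric, LOOCV accuracy per feature count.
#' @slot bestM Smallest feature count achieving the maximum accuracy.
#' @slot bestAccuracy Maximum accuracy over the grid.
#' @export
setClass("LoocvResult",
  slots = c(folds = "DataFrame", predictions = "matrix", features = "list",
            mGrid = "integer", accuracy = "numeric",
            bestM = "integer", bestAccuracy = "numeric"))

#' Consensus clustering result for one k
#'
#' Resampling-based cluster stability (Monti-style): entry (i, j) of the
#' consensus matrix is the fraction of resamples containing both samples i
#' and j in which the base clusterer co-assigned them.
#'
#' @slot consensus Symmetric samples-by-samples matrix, entries in \[0, 1\]
#'   (`NA` for pairs never co-sampled; a warning is emitted when that occurs).
#' @slot k Number of clusters.
#' @slot labels Integer cluster assignment from re-clustering the consensus
#'   matrix (as similarity) into k groups.
#' @slot nResamples,subsampleFraction,seed Resampling parameters.
#' @export
setClass("ConsensusResult",
  slots = c(consensus = "matrix", k = "integer", labels = "integer",
            nResamples = "integer", subsampleFraction = "numeric",
            seed = "integer"))

setValidity("ConsensusResult", function(object) {
  m <- object@consensus
  if (nrow(m) != ncol(m)) return("consensus matrix must be square")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    return("consensus matrix must be symmetric")
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("consensus entries must lie in [0, 1]")
  TRUE
})
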