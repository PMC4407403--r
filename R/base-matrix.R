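#' Probe-to-pseudogene membership test
#'
#' A probe measures a pseudogene when both lie on the same chromosome and
#' their closed intervals share at least one base pair. This is the default
#' membership rule behind [buildBaseMatrix()]; vectorized over pairs
#' (shorter argument recycled).
#'
#' @param probe,pseudogene `GRanges` of equal length (or length 1).
#' @return Logical vector.
#' @export
probeOverlaps <- function(probe, pseudogene) {
  as.character(seqnames(probe)) == as.character(seqnames(pseudogene)) &
    start(probe) <= end(pseudogene) &
    end(probe) >= start(pseudogene)
}

#' Build the sparse genes-by-probes base matrix
#'
#' Entry (j, i) is nonzero iff probe i falls in pseudogene j's extended
#' region. Under `scheme = "binary"` the weight is 1; under `"averaged"` it
#' is 1/k where k is the pseudogene's member-probe count, so the downstream
#' matrix product yields the mean of member probes. Overlap detection uses
#' an interval-tree query per chromosome (GenomicRanges), never an
#' all-pairs scan.
#'
#' @param annotation A [CnaAnnotation-class].
#' @param scheme `"binary"` or `"averaged"`.
#' @param overlapRule Membership rule: `"any"` (default, >= 1 bp shared),
#'   `"within"` (probe fully contained), or `"midpoint"` (probe midpoint
#'   inside the region).
#' @return A [BaseMatrix-class].
#' @export
buildBaseMatrix <- function(annotation, scheme = c("binary", "averaged"),
                            overlapRule = c("any", "within", "midpoint")) {
  scheme <- match.arg(scheme)
  overlapRule <- match.arg(overlapRule)
  pg <- pseudogenes(annotation)
  pr <- probes(annotation)
  if (length(pr) == 0) stop("empty probe table", call. = FALSE)

  q <- pr
  type <- "any"
  if (overlapRule == "within") type <- "within"
  if (overlapRule == "midpoint") {
    mid <- floor((start(pr) + end(pr)) / 2)
    q <- GRanges(seqnames(pr), IRanges(mid, mid))
    type <- "within"
  }
  hits <- findOverlaps(q, pg, type = type, ignore.strand = TRUE)

  n_g <- length(pg); n_p <- length(pr)
  k <- tabulate(S4Vectors::subjectHits(hits), n_g)
  w <- if (scheme == "binary") rep(1, length(hits))
       else 1 / k[S4Vectors::subjectHits(hits)]
  weights <- Matrix::sparseMatrix(
    i = S4Vectors::subjectHits(hits), j = S4Vectors::queryHits(hits),
    x = w, dims = c(n_g, n_p),
    dimnames = list(mcols(pg)$symbol, names(pr)))
  new("BaseMatrix", weights = methods::as(weights, "CsparseMatrix"),
      scheme = scheme, probeCounts = as.integer(k),
      probeWidths = as.integer(width(pr)))
}

#' Record member-probe counts on the annotation
#'
#' Copies the per-gene member-probe counts of a built base matrix onto the
#' pseudogene `probe_count` metadata column (used e.g. as the BED score).
#'
#' @param annotation A [CnaAnnotation-class].
#' @param bm The [BaseMatrix-class] built from it.
#' @return The updated `CnaAnnotation`.
#' @export
updateProbeCounts <- function(annotation, bm) {
  stopifnot(length(pseudogenes(annotation)) == nrow(bm))
  pg <- pseudogenes(annotation)
  mcols(pg)$probe_count <- probeCounts(bm)
  CnaAnnotation(pg, probes(annotation))
}

#' Summarize a base matrix
#'
#' Reports dimensions, member-probe count statistics over genes with at
#' least one member probe, the number of probe-free genes, and the mean
#' probe base-pair coverage per pseudogene (sum of member-probe lengths;
#' e.g. 37 probes of 60 bp cover 2,220 bp).
#'
#' @param bm A [BaseMatrix-class].
#' @return A list with elements `nGenes`, `nProbes`, `meanProbeCount`,
#'   `medianProbeCount`, `zeroProbeGenes`, `meanProbeCoverage` (statistics
#'   are `NA` when no gene has a member probe).
#' @export
matrixSummary <- function(bm) {
  k <- probeCounts(bm)
  nz <- k >= 1
  coverage <- as.numeric((baseWeights(bm) != 0) %*% bm@probeWidths)
  list(nGenes = nrow(bm), nProbes = ncol(bm),
       meanProbeCount = if (any(nz)) mean(k[nz]) else NA_real_,
       medianProbeCount = if (any(nz)) stats::median(k[nz]) else NA_real_,
       zeroProbeGenes = sum(!nz),
       meanProbeCoverage = if (any(nz)) mean(coverage[nz]) else NA_real_)
}

#' Persist / restore a base matrix
#'
#' The matrix is stored as coordinate-format triplets
#' (gene_symbol, probe_id, weight) with an index sidecar
#' (`<path>.index.tsv`) recording the scheme, the full gene and probe
#' orderings, member-probe counts and probe widths, so all-zero rows and
#' columns survive the round trip. Weights are printed with 17 significant
#' digits; the binary scheme round-trips bit-exactly.
#'
#' @param bm A [BaseMatrix-class].
#' @param path Triplet TSV path; the sidecar is written next to it.
#' @export
writeBaseMatrix <- function(bm, path) {
  w <- baseWeights(bm)
  tw <- methods::as(w, "TsparseMatrix")
  ord <- order(tw@i, tw@j)
  trip <- data.frame(gene_symbol = rownames(w)[tw@i[ord] + 1L],
                     probe_id = colnames(w)[tw@j[ord] + 1L],
                     weight = sprintf("%.17g", tw@x[ord]))
  utils::write.table(trip, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  idx <- rbind(
    data.frame(kind = "scheme", id = weightScheme(bm), value = ""),
    data.frame(kind = "gene", id = rownames(w),
               value = as.character(probeCounts(bm))),
    data.frame(kind = "probe", id = colnames(w),
               value = as.character(bm@probeWidths)))
  utils::write.table(idx, paste0(path, ".index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBaseMatrix
#' @export
readBaseMatrix <- function(path) {
  idx_path <- paste0(path, ".index.tsv")
  if (!file.exists(path) || !file.exists(idx_path))
    stop("base matrix files not found: ", path, call. = FALSE)
  idx <- utils::read.delim(idx_path, colClasses = "character",
                           quote = "", check.names = FALSE)
  scheme <- idx$id[idx$kind == "scheme"]
  genes <- idx$id[idx$kind == "gene"]
  k <- as.integer(idx$value[idx$kind == "gene"])
  probe_ids <- idx$id[idx$kind == "probe"]
  widths <- as.integer(idx$value[idx$kind == "probe"])
  trip <- utils::read.delim(path, colClasses = "character", quote = "",
                            check.names = FALSE)
  weights <- Matrix::sparseMatrix(
    i = match(trip$gene_symbol, genes),
    j = match(trip$probe_id, probe_ids),
    x = as.numeric(trip$weight),
    dims = c(length(genes), length(probe_ids)),
    dimnames = list(genes, probe_ids))
  new("BaseMatrix", weights = methods::as(weights, "CsparseMatrix"),
      scheme = scheme, probeCounts = k, probeWidths = widths)
}

#' @rdname BaseMatrix-class
#' @export
setMethod("baseWeights", "BaseMatrix", function(x) x@weights)

#' @rdname BaseMatrix-class
#' @export
setMethod("weightScheme", "BaseMatrix", function(x) x@scheme)

#' @rdname BaseMatrix-class
#' @export
setMethod("probeCounts", "BaseMatrix", function(x)
  stats::setNames(x@probeCounts, rownames(x@weights)))

#' @rdname BaseMatrix-class
#' @export
setMethod("dim", "BaseMatrix", function(x) dim(x@weights))

#' @rdname BaseMatrix-class
#' @export
setMethod("dimnames", "BaseMatrix", function(x) dimnames(x@weights))

setMethod("show", "BaseMatrix", function(object) {
  s <- matrixSummary(object)
  cat(sprintf("BaseMatrix (%s): %d genes x %d probes, %d stored weights\n",
              object@scheme, s$nGenes, s$nProbes,
              length(object@weights@x)))
  if (!is.na(s$meanProbeCount))
    cat(sprintf("  mean member probes/gene: %.2f; probe-free genes: %d\n",
                s$meanProbeCount, s$zeroProbeGenes))
})
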