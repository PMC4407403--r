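#' Read a gene annotation table
#'
#' Parses a BioMart-style TSV of gene coordinates into a `GRanges`.
#' Coordinates are 1-based inclusive throughout the package, matching
#' genome-browser `chrN:start-end` notation; [exportPseudogeneBed()] converts
#' to BED's 0-based half-open convention on export.
#'
#' Rows with missing or malformed coordinates (non-numeric, `start < 1`,
#' `end < start`) are skipped and the skip count reported. A blank or
#' unrecognized strand is mapped to `"*"` (unknown).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Named list mapping the roles `symbol`, `chrom`, `start`,
#'   `end`, `strand` to column names in the file.
#' @return A `GRanges` with metadata column `symbol`, in file order.
#' @export
readGeneAnnotation <- function(path,
                               dialect = list(symbol = "symbol",
                                              chrom = "chrom",
                                              start = "start",
                                              end = "end",
                                              strand = "strand")) {
  df <- read_annotation_tsv(path)
  need <- c("symbol", "chrom", "start", "end")
  cols <- vapply(need, function(r) dialect[[r]] %||% r, character(1))
  if (!all(cols %in% names(df)))
    stop("gene annotation: cannot map columns ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  strand_col <- dialect[["strand"]] %||% "strand"
  strand_raw <- if (strand_col %in% names(df)) as.character(df[[strand_col]])
                else rep(NA_character_, nrow(df))

  symbol <- as.character(df[[cols["symbol"]]])
  chrom <- as.character(df[[cols["chrom"]]])
  start <- suppressWarnings(as.numeric(df[[cols["start"]]]))
  end <- suppressWarnings(as.numeric(df[[cols["end"]]]))

  ok <- !is.na(symbol) & nzchar(symbol) & !is.na(chrom) & nzchar(chrom) &
    !is.na(start) & !is.na(end) & start >= 1 & end >= start
  n_skip <- sum(!ok)
  if (n_skip > 0)
    message("readGeneAnnotation: skipped ", n_skip,
            " row(s) with missing or malformed coordinates")
  if (!any(ok))
    stop("gene annotation: no valid rows in ", path, call. = FALSE)

  strand <- strand_raw[ok]
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  GRanges(chrom[ok], IRanges(start[ok], end[ok]), strand = strand,
          symbol = symbol[ok])
}

#' Read a probe annotation table
#'
#' Parses the array's probe layout (probe id plus genomic interval; 60 bp
#' probes on the Agilent 244A design, though length is not enforced).
#' Duplicate probe ids keep the first occurrence with a warning; when more
#' than `maxDuplicateFraction` of rows are duplicates the file is rejected.
#'
#' @param path TSV with header; columns per `dialect`.
#' @param dialect Named list mapping `probe_id`, `chrom`, `start`, `end`.
#' @param maxDuplicateFraction Fatal threshold on the duplicate-row fraction.
#' @return A `GRanges` named by probe id, in file order.
#' @export
readProbeAnnotation <- function(path,
                                dialect = list(probe_id = "probe_id",
                                               chrom = "chrom",
                                               start = "start",
                                               end = "end"),
                                maxDuplicateFraction = 0.01) {
  df <- read_annotation_tsv(path)
  need <- c("probe_id", "chrom", "start", "end")
  cols <- vapply(need, function(r) dialect[[r]] %||% r, character(1))
  if (!all(cols %in% names(df)))
    stop("probe annotation: cannot map columns ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)

  id <- as.character(df[[cols["probe_id"]]])
  chrom <- as.character(df[[cols["chrom"]]])
  start <- suppressWarnings(as.numeric(df[[cols["start"]]]))
  end <- suppressWarnings(as.numeric(df[[cols["end"]]]))

  ok <- !is.na(id) & nzchar(id) & !is.na(chrom) & nzchar(chrom) &
    !is.na(start) & !is.na(end) & start >= 1 & end >= start
  if (any(!ok))
    message("readProbeAnnotation: skipped ", sum(!ok), " malformed row(s)")
  if (!any(ok)) stop("probe annotation: no valid rows in ", path,
                     call. = FALSE)
  id <- id[ok]; chrom <- chrom[ok]; start <- start[ok]; end <- end[ok]

  dup <- duplicated(id)
  if (any(dup)) {
    frac <- mean(dup)
    if (frac > maxDuplicateFraction)
      stop(sprintf(
        "probe annotation: %.1f%% duplicate probe ids exceeds the %.1f%% limit",
        100 * frac, 100 * maxDuplicateFraction), call. = FALSE)
    warning(sum(dup), " duplicate probe id row(s) dropped (first kept)",
            call. = FALSE)
  }
  gr <- GRanges(chrom[!dup], IRanges(start[!dup], end[!dup]))
  names(gr) <- id[!dup]
  gr
}

read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deduplicate gene records by symbol
#'
#' Annotation exports frequently carry several records per symbol (alternate
#' assemblies, patches). One record per symbol is kept: the longest interval,
#' ties broken by smallest start, then lexicographically smallest chromosome.
#' Input order of the surviving records is preserved, so the operation is
#' idempotent.
#'
#' @param genes `GRanges` with a `symbol` metadata column.
#' @return `GRanges` with unique symbols; the dropped count is reported.
#' @export
deduplicateGenes <- function(genes) {
  stopifnot(is(genes, "GRanges"), "symbol" %in% names(mcols(genes)))
  sym <- mcols(genes)$symbol
  if (!anyDuplicated(sym)) return(genes)
  pref <- order(sym, -width(genes), start(genes),
                as.character(seqnames(genes)))
  keep_first <- pref[!duplicated(sym[pref])]
  dropped <- length(genes) - length(keep_first)
  message("deduplicateGenes: dropped ", dropped, " duplicate record(s)")
  genes[sort(keep_first)]
}

#' Extend gene regions into probe-capture pseudogenes
#'
#' Each gene interval is widened by `flank` bp on both sides plus
#' `promoter` bp on the upstream (promoter) side -- the 5' side on the `+`
#' strand, the 3' coordinate side on the `-` strand. For strand-unknown
#' genes, and always when `strandAwarePromoter = FALSE`, the promoter
#' allowance is applied on both sides. The result is the extended capture
#' window within which array probes are counted as measuring the gene.
#'
#' Defaults (100 kb flank, 2 kb promoter) reflect that copy-number events
#' are typically far larger than a gene body, so probes well outside the
#' gene still carry its copy-number signal.
#'
#' @param genes `GRanges` with `symbol` metadata (deduplicated).
#' @param flank Flanking extension in bp on each side (default 100000).
#' @param promoter Promoter allowance in bp (default 2000).
#' @param chromosomeLengths Optional named vector; extended ends are clamped
#'   to these lengths. Starts are always clamped to 1.
#' @param strandAwarePromoter If `FALSE`, apply the promoter symmetrically
#'   regardless of strand.
#' @return `GRanges` of pseudogenes with metadata `symbol`, `gene_start`,
#'   `gene_end`, `probe_count` (`NA` until a base matrix is built).
#' @examples
#' g <- GRanges("chr1", IRanges(500000, 510000), strand = "+",
#'              symbol = "GENE1")
#' extendGenes(g)  # chr1:398000-610000
#' @export
extendGenes <- function(genes, flank = 100000, promoter = 2000,
                        chromosomeLengths = NULL,
                        strandAwarePromoter = TRUE) {
  stopifnot(is(genes, "GRanges"), "symbol" %in% names(mcols(genes)),
            flank >= 0, promoter >= 0)
  s <- start(genes); e <- end(genes)
  str <- as.character(strand(genes))
  up <- if (strandAwarePromoter) ifelse(str == "-", 0, promoter)
        else promoter
  dn <- if (strandAwarePromoter) ifelse(str == "-", promoter,
                                        ifelse(str == "+", 0, promoter))
        else promoter
  new_start <- pmax(1, s - flank - up)
  new_end <- e + flank + dn
  if (!is.null(chromosomeLengths)) {
    chrom <- as.character(seqnames(genes))
    has_len <- chrom %in% names(chromosomeLengths)
    new_end[has_len] <- pmin(new_end[has_len],
                             chromosomeLengths[chrom[has_len]])
  }
  out <- GRanges(seqnames(genes), IRanges(new_start, new_end),
                 strand = strand(genes))
  mcols(out) <- DataFrame(symbol = mcols(genes)$symbol,
                          gene_start = s, gene_end = e,
                          probe_count = NA_integer_)
  out
}

#' Construct a CnaAnnotation
#'
#' @param pseudogenes `GRanges` from [extendGenes()].
#' @param probes Named `GRanges` from [readProbeAnnotation()] (or with a
#'   `probe_id` metadata column, promoted to names).
#' @return A [CnaAnnotation-class] object.
#' @export
CnaAnnotation <- function(pseudogenes, probes) {
  if (is.null(names(probes)) && "probe_id" %in% names(mcols(probes))) {
    names(probes) <- mcols(probes)$probe_id
    mcols(probes)$probe_id <- NULL
  }
  new("CnaAnnotation", pseudogenes = pseudogenes, probes = probes)
}

#' @rdname CnaAnnotation-class
#' @export
setMethod("pseudogenes", "CnaAnnotation", function(x) x@pseudogenes)

#' @rdname CnaAnnotation-class
#' @export
setMethod("probes", "CnaAnnotation", function(x) x@probes)

setMethod("show", "CnaAnnotation", function(object) {
  cat("CnaAnnotation:", length(object@pseudogenes), "pseudogenes,",
      length(object@probes), "probes\n")
  k <- mcols(object@pseudogenes)$probe_count
  if (!all(is.na(k)))
    cat("  mean member-probe count:",
        round(mean(k[!is.na(k)]), 2), "\n")
})

#' Export pseudogenes as a BED track
#'
#' Writes the extended regions in BED format (0-based half-open, handled by
#' rtracklayer): name = gene symbol, score = member-probe count (0 when not
#' yet computed), strand preserved.
#'
#' @param x A [CnaAnnotation-class] or a pseudogene `GRanges`.
#' @param path Output BED file.
#' @export
exportPseudogeneBed <- function(x, path) {
  gr <- if (is(x, "CnaAnnotation")) pseudogenes(x) else x
  k <- mcols(gr)$probe_count
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  mcols(out)$name <- mcols(gr)$symbol
  mcols(out)$score <- ifelse(is.na(k), 0L, k)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Write gene / probe annotation tables
#'
#' Serializers matching the formats read by [readGeneAnnotation()] and
#' [readProbeAnnotation()]; parse -> write -> parse round-trips exactly.
#'
#' @param genes,probes `GRanges` as returned by the readers.
#' @param path Output TSV path.
#' @export
writeGeneAnnotation <- function(genes, path) {
  df <- data.frame(symbol = mcols(genes)$symbol,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes), end = end(genes),
                   strand = as.character(strand(genes)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneAnnotation
#' @export
writeProbeAnnotation <- function(probes, path) {
  df <- data.frame(probe_id = names(probes),
                   chrom = as.character(seqnames(probes)),
                   start = start(probes), end = end(probes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
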