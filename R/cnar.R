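#' Read a probe-level CNA matrix
#'
#' Reads a probes-by-samples TSV of log2 ratios: first column the probe id,
#' header row the sample ids. Empty cells and the sentinel `NA` are treated
#' as missing. Per-sample missingness fractions are reported when any value
#' is missing.
#'
#' @param path Input TSV.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
readCnaMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty CNA file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  n_s <- length(samples)
  body <- fields[-1]
  nf <- lengths(body)
  bad <- which(nf != n_s + 1L)
  if (length(bad))
    stop("CNA row ", bad[1] + 1L, ": expected ", n_s + 1L,
         " fields, found ", nf[bad[1]], call. = FALSE)
  probe_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids in CNA matrix", call. = FALSE)
  vals <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals[vals == "" | vals == "NA"] <- NA_character_
  m <- matrix(as.numeric(vals), nrow = length(body), ncol = n_s,
              byrow = TRUE, dimnames = list(probe_ids, samples))
  if (anyNA(m)) {
    frac <- colMeans(is.na(m))
    message("readCnaMatrix: per-sample missing fractions: ",
            paste(sprintf("%s=%.3g", samples, frac), collapse = ", "))
  }
  m
}

#' Write a probes-by-samples (or genes-by-samples) matrix as TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param idColumn Name of the first (row id) column.
#' @param digits Significant digits (default 17: exact double round trip).
#' @export
writeCnaMatrix <- function(m, path, idColumn = "probe_id", digits = 17) {
  txt <- matrix(sprintf("%.*g", digits, m), nrow = nrow(m))
  txt[is.na(m)] <- "NA"
  out <- cbind(rownames(m), txt)
  colnames(out) <- c(idColumn, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate the gene-level CNAR matrix
#'
#' The core transform: the genes-by-samples CNAR matrix is the product of
#' the base matrix C and the probes-by-samples CNA matrix D,
#' CNAR\[g, s\] = sum_i C\[g, i\] D\[i, s\]. With the binary scheme this is
#' the sum of member-probe values; with the averaged scheme, their mean.
#' Missing probe values are excluded: under the averaged scheme the weights
#' are renormalized per gene and sample over the observed member probes (the
#' value remains the mean of observed members), and under the binary scheme
#' the sum runs over observed members. A gene with no member probes, or all
#' member probes missing in a sample, yields `NA`.
#'
#' Probe sets are reconciled by exact id match; probes present on only one
#' side are dropped with a message. An empty intersection is an error.
#'
#' @param bm A [BaseMatrix-class].
#' @param cna Probes-by-samples numeric matrix from [readCnaMatrix()] (or
#'   [simulateCna()]).
#' @param labels Optional per-sample class labels (named factor or vector in
#'   sample order), stored in `colData(x)$class`.
#' @return A [CnarExperiment-class].
#' @export
generateCnar <- function(bm, cna, labels = NULL) {
  common <- intersect(colnames(bm), rownames(cna))
  if (length(common) == 0)
    stop("no probe ids shared between base matrix and CNA matrix",
         call. = FALSE)
  drop_bm <- ncol(bm) - length(common)
  drop_cna <- nrow(cna) - length(common)
  if (drop_bm > 0 || drop_cna > 0)
    message("generateCnar: dropped ", drop_bm,
            " base-matrix probe(s) and ", drop_cna,
            " CNA probe(s) absent from the other side")

  W <- baseWeights(bm)[, common, drop = FALSE]
  D <- cna[common, , drop = FALSE]
  P <- W
  P@x <- rep(1, length(P@x))   # membership pattern
  D0 <- D
  D0[is.na(D0)] <- 0
  obs <- !is.na(D)
  storage.mode(obs) <- "double"
  S <- as.matrix(P %*% D0)     # sum over observed member probes
  N <- as.matrix(P %*% obs)    # number of observed member probes

  vals <- if (weightScheme(bm) == "binary") S else S / N
  vals[N == 0] <- NA_real_
  dimnames(vals) <- list(rownames(bm), colnames(cna))

  CnarExperiment(vals, scheme = weightScheme(bm),
                 probeCount = probeCounts(bm), labels = labels)
}

#' Construct a CnarExperiment
#'
#' @param values Genes-by-samples numeric matrix (dimnames required).
#' @param scheme `"binary"` or `"averaged"`.
#' @param probeCount Optional per-gene member-probe counts.
#' @param labels Optional per-sample class labels; if named, matched to
#'   sample ids (every sample must be covered), else taken in column order.
#' @return A [CnarExperiment-class].
#' @export
CnarExperiment <- function(values, scheme, probeCount = NULL,
                           labels = NULL) {
  rd <- DataFrame(symbol = rownames(values))
  if (!is.null(probeCount)) rd$probe_count <- as.integer(probeCount)
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      miss <- setdiff(colnames(values), names(labels))
      if (length(miss))
        stop("no class label for sample(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      labels <- labels[colnames(values)]
    } else stopifnot(length(labels) == ncol(values))
    cd$class <- factor(as.character(labels),
                       levels = unique(as.character(labels)))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cnar = values), rowData = rd, colData = cd)
  new("CnarExperiment", se, scheme = scheme)
}

#' @rdname CnarExperiment
#' @param x A `CnarExperiment`.
#' @export
cnarValues <- function(x) SummarizedExperiment::assay(x, "cnar")

#' @rdname CnarExperiment
#' @export
setMethod("weightScheme", "CnarExperiment", function(x) x@scheme)

#' @rdname CnarExperiment
#' @export
sampleClasses <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"class" %in% names(cd)) return(NULL)
  stats::setNames(cd$class, rownames(cd))
}

setMethod("show", "CnarExperiment", function(object) {
  cat(sprintf("CnarExperiment (%s scheme): %d genes x %d samples\n",
              object@scheme, nrow(object), ncol(object)))
  v <- cnarValues(object)
  cat(sprintf("  missing: %.2f%%; value range: [%.3g, %.3g]\n",
              100 * mean(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  cls <- sampleClasses(object)
  if (!is.null(cls))
    cat("  classes:", paste(sprintf("%s=%d", levels(cls),
                                    table(cls)), collapse = ", "), "\n")
})

#' Filter genes by across-sample variance
#'
#' Keeps genes whose unbiased sample variance across samples (missing values
#' excluded) exceeds `cutoff`; the conventional cutoff for these gene-level
#' copy-number matrices is 0.4. Genes with fewer than two observed values
#' cannot be assessed and are dropped and counted separately.
#'
#' @param x A [CnarExperiment-class] or genes-by-samples matrix.
#' @param cutoff Non-negative threshold (default 0.4), strict (`>`).
#' @param statistic `"variance"` (default) or `"sd"`, in case a standard
#'   deviation cutoff is wanted instead.
#' @return The filtered object of the same class. The report (counts kept /
#'   below cutoff / degenerate) is attached as
#'   `metadata(x)$varianceFilter` for experiments, `attr(x,
#'   "varianceFilter")` for matrices, and is also messaged.
#' @export
varianceFilter <- function(x, cutoff = 0.4,
                           statistic = c("variance", "sd")) {
  statistic <- match.arg(statistic)
  stopifnot(cutoff >= 0)
  m <- if (is(x, "CnarExperiment")) cnarValues(x) else x
  n_obs <- rowSums(!is.na(m))
  v <- row_vars_na(m)
  stat <- if (statistic == "sd") sqrt(v) else v
  degenerate <- n_obs < 2
  keep <- !degenerate & !is.na(stat) & stat > cutoff
  report <- list(kept = sum(keep),
                 belowCutoff = sum(!keep & !degenerate),
                 degenerate = sum(degenerate),
                 cutoff = cutoff, statistic = statistic)
  message(sprintf(
    "varianceFilter: kept %d/%d genes (%s > %g); %d degenerate",
    report$kept, nrow(m), statistic, cutoff, report$degenerate))
  out <- x[keep, , drop = FALSE]
  if (is(out, "CnarExperiment"))
    S4Vectors::metadata(out)$varianceFilter <- report
  else attr(out, "varianceFilter") <- report
  out
}
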