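#' Silhouette widths for a clustering
#'
#' Per-sample silhouette s(i) = (b_i - a_i) / max(a_i, b_i), where a_i is
#' the mean distance to the sample's own cluster and b_i the smallest mean
#' distance to another cluster; samples in singleton clusters get s(i) = 0.
#' Distances are Euclidean when computed from data. Computation is delegated
#' to [cluster::silhouette()].
#'
#' @param x A [CnarExperiment-class] (samples, i.e. columns, are the
#'   clustered units), an observations-by-features matrix, or a `dist`.
#' @param labels Cluster assignment (>= 2 distinct clusters).
#' @return List with `widths` (named numeric per sample), `clusters`
#'   (integer assignment) and `mean` (mean silhouette width over all
#'   samples).
#' @export
silhouetteWidth <- function(x, labels) {
  d <- if (inherits(x, "dist")) x
       else if (is(x, "CnarExperiment")) stats::dist(t(cnarValues(x)))
       else stats::dist(x)
  cl <- as.integer(factor(labels))
  n <- attr(d, "Size")
  stopifnot(length(cl) == n)
  if (length(unique(cl)) < 2)
    stop("silhouette requires at least two clusters", call. = FALSE)
  sil <- cluster::silhouette(cl, d)
  widths <- sil[, "sil_width"]
  names(widths) <- attr(d, "Labels") %||% as.character(seq_len(n))
  list(widths = widths, clusters = cl, mean = mean(widths))
}

#' Consensus clustering by subsampling
#'
#' Monti-style cluster-stability assessment: the cohort is repeatedly
#' subsampled without replacement, the base clusterer is run on each
#' subsample, and the consensus matrix records, for every sample pair, the
#' fraction of co-sampled resamples in which the pair was co-clustered.
#' Final labels for each k come from re-clustering `1 - consensus` as a
#' distance. Defaults follow common practice: 100 resamples at an 0.8
#' subsample fraction with hierarchical agglomerative clustering (average
#' linkage, Euclidean distance) as the base clusterer.
#'
#' @param x A [CnarExperiment-class] (columns are clustered), an
#'   observations-by-features matrix, or `dist` is not accepted here
#'   (subsampling needs the data).
#' @param kRange Integer vector of cluster numbers to evaluate.
#' @param nResamples Number of subsampling iterations (>= 1).
#' @param subsampleFraction Fraction of samples drawn per iteration
#'   (0 < f <= 1).
#' @param clusterFun Base clusterer `function(d, k) -> integer labels`
#'   taking a `dist` over the subsample; default hierarchical/average.
#' @param seed Integer seed; the whole procedure is reproducible given it.
#' @return Named list (`"k2"`, `"k3"`, ...) of
#'   [ConsensusResult-class] objects.
#' @export
consensusCluster <- function(x, kRange = 2:4, nResamples = 100,
                             subsampleFraction = 0.8,
                             clusterFun = NULL, seed) {
  data <- if (is(x, "CnarExperiment")) t(cnarValues(x)) else as.matrix(x)
  stopifnot(nResamples >= 1,
            subsampleFraction > 0, subsampleFraction <= 1)
  seed <- as.integer(seed)
  kRange <- as.integer(kRange)
  if (is.null(clusterFun))
    clusterFun <- function(d, k) stats::cutree(stats::hclust(
      d, method = "average"), k)
  n <- nrow(data)
  ids <- rownames(data) %||% as.character(seq_len(n))
  size <- max(2L, floor(subsampleFraction * n))

  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(kRange, function(k) matrix(0, n, n))
  withr::with_seed(seed, {
    for (r in seq_len(nResamples)) {
      idx <- sort(sample.int(n, size))
      d <- stats::dist(data[idx, , drop = FALSE])
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      for (j in seq_along(kRange)) {
        cl <- clusterFun(d, kRange[j])
        same <- outer(cl, cl, `==`) * 1
        co_clustered[[j]][idx, idx] <- co_clustered[[j]][idx, idx] + same
      }
    }
  })

  if (any(co_sampled[upper.tri(co_sampled)] == 0))
    warning("some sample pairs were never co-sampled; ",
            "their consensus entries are NA", call. = FALSE)

  out <- lapply(seq_along(kRange), function(j) {
    cons <- co_clustered[[j]] / co_sampled
    cons[co_sampled == 0] <- NA_real_
    dimnames(cons) <- list(ids, ids)
    cc <- cons
    cc[is.na(cc)] <- 0
    labels <- stats::cutree(stats::hclust(stats::as.dist(1 - cc),
                                          method = "average"), kRange[j])
    names(labels) <- ids
    new("ConsensusResult", consensus = cons, k = kRange[j],
        labels = as.integer(labels), nResamples = as.integer(nResamples),
        subsampleFraction = subsampleFraction, seed = seed)
  })
  names(out) <- paste0("k", kRange)
  out
}

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)

#' @rdname ConsensusResult-class
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x)
  stats::setNames(x@labels, rownames(x@consensus)))

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: k = %d, %d samples, %d resamples (fraction %.2f)\n",
    object@k, nrow(object@consensus), object@nResamples,
    object@subsampleFraction))
  cat("  cluster sizes:",
      paste(table(object@labels), collapse = ", "), "\n")
})
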