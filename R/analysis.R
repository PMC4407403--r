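#' Fisher criterion score for one gene
#'
#' Class-separation score (muA - muB)^2 / (sA^2 + sB^2), the squared
#' difference of class means over the summed unbiased class variances. A
#' small `epsilon` is added to the denominator so genes with zero variance
#' in both classes score finitely (1/epsilon when the means differ by 1);
#' set `epsilon = 0` to obtain `Inf` for such genes instead.
#'
#' @param valuesA,valuesB Numeric values for the two classes; missing values
#'   are dropped per class.
#' @param epsilon Denominator guard (default 1e-12).
#' @return A list with `meanA`, `meanB`, `varA`, `varB`, `score`. When a
#'   class retains fewer than two observations the score is `NA` (the gene
#'   is excluded from ranking).
#' @examples
#' fisherScore(c(0, 2), c(4, 6))$score  # (1-5)^2 / (2+2) = 4
#' @export
fisherScore <- function(valuesA, valuesB, epsilon = 1e-12) {
  stopifnot(epsilon >= 0)
  a <- valuesA[is.finite(valuesA)]
  b <- valuesB[is.finite(valuesB)]
  if (length(a) < 2 || length(b) < 2)
    return(list(meanA = NA_real_, meanB = NA_real_, varA = NA_real_,
                varB = NA_real_, score = NA_real_))
  mA <- mean(a); mB <- mean(b)
  vA <- stats::var(a); vB <- stats::var(b)
  list(meanA = mA, meanB = mB, varA = vA, varB = vB,
       score = (mA - mB)^2 / (vA + vB + epsilon))
}

#' Rank genes by Fisher criterion
#'
#' Scores every gene's separation between the two sample classes and sorts
#' by descending score; ties are broken by ascending gene symbol so the
#' ranking is deterministic. Genes for which either class has fewer than two
#' observed values are scored `NA` and placed, unranked, after all ranked
#' genes.
#'
#' @param x A [CnarExperiment-class] (classes taken from
#'   `colData(x)$class` unless `labels` is given) or a genes-by-samples
#'   matrix.
#' @param labels Two-class labels per sample (vector/factor; named vectors
#'   are matched to sample ids).
#' @param epsilon Passed to the score denominator; see [fisherScore()].
#' @return A `DataFrame` sorted by rank with columns `symbol`, `mean_A`,
#'   `mean_B`, `var_A`, `var_B`, `score`, `rank`; the class names behind A
#'   and B are in `metadata()$classes`.
#' @export
rankFeatures <- function(x, labels = NULL, epsilon = 1e-12) {
  m <- if (is(x, "CnarExperiment")) cnarValues(x) else x
  labels <- resolve_labels(m, x, labels)
  if (nlevels(labels) != 2)
    stop("rankFeatures requires exactly two classes, got ",
         nlevels(labels), call. = FALSE)
  if (any(table(labels) < 2))
    stop("each class needs at least 2 samples", call. = FALSE)

  idxA <- labels == levels(labels)[1]
  mA <- m[, idxA, drop = FALSE]
  mB <- m[, !idxA, drop = FALSE]
  nA <- rowSums(!is.na(mA)); nB <- rowSums(!is.na(mB))
  muA <- row_means_na(mA); muB <- row_means_na(mB)
  vA <- row_vars_na(mA); vB <- row_vars_na(mB)
  score <- (muA - muB)^2 / (vA + vB + epsilon)
  score[nA < 2 | nB < 2] <- NA_real_

  symbol <- rownames(m)
  ord <- order(-score, symbol, na.last = TRUE)
  out <- DataFrame(symbol = symbol[ord],
                   mean_A = muA[ord], mean_B = muB[ord],
                   var_A = vA[ord], var_B = vB[ord],
                   score = score[ord],
                   rank = NA_integer_)
  ranked <- !is.na(out$score)
  out$rank[ranked] <- seq_len(sum(ranked))
  rownames(out) <- out$symbol
  S4Vectors::metadata(out)$classes <- levels(labels)
  out
}

#' Linear soft-margin SVM classifier factory
#'
#' Default two-class learner for [loocvClassify()]: a linear-kernel
#' soft-margin SVM with fixed cost. Features are standardized to the
#' training mean and SD before fitting (gene-level copy-number features
#' have SDs far below 1, and without standardization the margin penalty
#' dominates and the fit collapses toward a constant majority-class
#' classifier). Constant features carry no information and are dropped;
#' training sets whose features are all constant fall back to the majority
#' training class. The returned function follows the pluggable-classifier
#' contract: `f(train, labels)` (samples x features) returns a prediction
#' function over new samples.
#'
#' @param cost Soft-margin regularization constant (default 1).
#' @return A classifier function.
#' @export
svmClassifier <- function(cost = 1) {
  function(train, labels) {
    labels <- droplevels(as.factor(labels))
    keep <- apply(train, 2, function(v) max(v) - min(v) > 0)
    if (!any(keep)) {
      maj <- names(which.max(table(labels)))
      return(function(newx)
        factor(rep(maj, nrow(newx)), levels = levels(labels)))
    }
    fit <- e1071::svm(train[, keep, drop = FALSE], labels,
                      kernel = "linear", cost = cost, scale = TRUE)
    function(newx) stats::predict(fit, newx[, keep, drop = FALSE])
  }
}

#' Leave-one-out cross-validated classification with nested feature
#' selection
#'
#' Evaluates two-class prediction from gene-level copy number under strict
#' LOOCV: for every fold the Fisher ranking and the classifier are
#' recomputed on the n - 1 training samples only, the top-m genes are
#' selected for every candidate m in `mGrid`, and the held-out sample is
#' predicted. The held-out sample is never visible to ranking or training,
#' so feature selection cannot leak. `bestM` is the smallest feature count
#' achieving the maximum LOOCV accuracy.
#'
#' Missing values are imputed with the training-fold feature mean before
#' fitting (0 when a feature is entirely missing in training).
#'
#' @param x A [CnarExperiment-class] or genes-by-samples matrix.
#' @param labels Two-class sample labels (see [rankFeatures()]).
#' @param mGrid Integer vector of candidate feature counts (each <= number
#'   of rankable genes).
#' @param classifier Classifier factory output; see [svmClassifier()].
#' @param epsilon Fisher denominator guard.
#' @return A [LoocvResult-class].
#' @export
loocvClassify <- function(x, labels = NULL, mGrid = 1:10,
                          classifier = svmClassifier(),
                          epsilon = 1e-12) {
  m <- if (is(x, "CnarExperiment")) cnarValues(x) else x
  labels <- resolve_labels(m, x, labels)
  n <- ncol(m)
  if (n < 4) stop("LOOCV needs at least 4 samples", call. = FALSE)
  mGrid <- sort(unique(as.integer(mGrid)))
  if (any(mGrid < 1) || any(mGrid > nrow(m)))
    stop("mGrid entries must lie in [1, n_genes]", call. = FALSE)
  maxM <- max(mGrid)

  preds <- matrix(NA_character_, n, length(mGrid),
                  dimnames = list(colnames(m), paste0("m", mGrid)))
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    tr_lab <- droplevels(labels[-i])
    if (nlevels(tr_lab) < 2)
      stop("a class is absent from the training fold for sample ",
           colnames(m)[i], call. = FALSE)
    ranking <- rankFeatures(m[, -i, drop = FALSE], labels[-i],
                            epsilon = epsilon)
    top <- ranking$symbol[!is.na(ranking$rank)]
    if (length(top) < maxM)
      stop("only ", length(top), " rankable genes in fold ", i,
           " but mGrid asks for ", maxM, call. = FALSE)
    feats[[i]] <- top[seq_len(maxM)]
    for (j in seq_along(mGrid)) {
      genes <- top[seq_len(mGrid[j])]
      tr <- t(m[genes, -i, drop = FALSE])
      te <- t(m[genes, i, drop = FALSE])
      fmeans <- colMeans(tr, na.rm = TRUE)
      fmeans[is.na(fmeans)] <- 0
      for (g in seq_along(genes)) {
        tr[is.na(tr[, g]), g] <- fmeans[g]
        te[is.na(te[, g]), g] <- fmeans[g]
      }
      model <- classifier(tr, labels[-i])
      preds[i, j] <- as.character(model(te))
    }
  }

  acc <- colMeans(preds == as.character(labels))
  names(acc) <- paste0("m", mGrid)
  best_j <- which(acc == max(acc))[1]
  folds <- DataFrame(sample = colnames(m),
                     true = as.character(labels),
                     predicted = preds[, best_j])
  new("LoocvResult", folds = folds, predictions = preds,
      features = feats, mGrid = mGrid, accuracy = acc,
      bestM = mGrid[best_j], bestAccuracy = unname(acc[best_j]))
}

resolve_labels <- function(m, x, labels) {
  if (is.null(labels) && is(x, "CnarExperiment"))
    labels <- sampleClasses(x)
  if (is.null(labels))
    stop("class labels are required", call. = FALSE)
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(m), names(labels))
    if (length(miss))
      stop("no class label for sample(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    labels <- labels[colnames(m)]
  } else stopifnot(length(labels) == ncol(m))
  factor(as.character(labels), levels = unique(as.character(labels)))
}

#' @rdname LoocvResult-class
#' @export
setMethod("bestM", "LoocvResult", function(x) x@bestM)

#' @rdname LoocvResult-class
#' @export
setMethod("bestAccuracy", "LoocvResult", function(x) x@bestAccuracy)

#' @rdname LoocvResult-class
#' @export
setMethod("foldAccuracy", "LoocvResult", function(x) x@accuracy)

setMethod("show", "LoocvResult", function(object) {
  cat(sprintf(
    "LoocvResult: %d folds; best accuracy %.4f at m = %d features\n",
    nrow(object@folds), object@bestAccuracy, object@bestM))
  cat("  accuracy by m:",
      paste(sprintf("%s=%.3f", names(object@accuracy), object@accuracy),
            collapse = " "), "\n")
})
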