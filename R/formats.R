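#' GCT export / import
#'
#' Writes a genes-by-samples matrix in GCT v1.2, the tab-delimited layout
#' expected by GenePattern and GSEA: line 1 `#1.2`, line 2 the row and
#' column counts, then a header `NAME<TAB>Description<TAB>samples...`. The
#' Description column is filled with the gene symbol. Values are rendered
#' with 17 significant digits by default so a write-then-read round trip
#' reproduces them exactly; missing values are written as `NA`.
#'
#' @param x A [CnarExperiment-class] or numeric matrix with dimnames.
#' @param path Output file.
#' @param digits Significant digits for values.
#' @export
writeGct <- function(x, path, digits = 17) {
  m <- if (is(x, "CnarExperiment")) cnarValues(x) else x
  if (nrow(m) == 0 || ncol(m) == 0)
    stop("refusing to write an empty GCT matrix", call. = FALSE)
  txt <- matrix(sprintf("%.*g", digits, m), nrow = nrow(m))
  txt[is.na(m)] <- "NA"
  rows <- paste(rownames(m), rownames(m),
                apply(txt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c("#1.2",
               paste(nrow(m), ncol(m), sep = "\t"),
               paste(c("NAME", "Description", colnames(m)),
                     collapse = "\t"),
               rows), path)
  invisible(path)
}

#' @rdname writeGct
#' @return `readGct` returns the numeric matrix (genes x samples).
#' @export
readGct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#1.2"))
    stop("not a GCT v1.2 file: ", path, call. = FALSE)
  dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:2)]
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  if (length(body) != dims[1])
    stop("GCT row count mismatch: declared ", dims[1], ", found ",
         length(body), call. = FALSE)
  vals <- unlist(lapply(body, `[`, -(1:2)), use.names = FALSE)
  vals[vals == "" | vals == "NA"] <- NA_character_
  matrix(as.numeric(vals), nrow = dims[1], ncol = dims[2], byrow = TRUE,
         dimnames = list(vapply(body, `[[`, character(1), 1L), samples))
}

#' CLS phenotype export / import
#'
#' Categorical CLS layout: line 1 `n_samples n_classes 1`, line 2 `#`
#' followed by the class names in order of first appearance, line 3 the
#' 0-based class index of each sample in order.
#'
#' @param labels Class labels in sample order (vector or factor). If
#'   `samples` is given, `labels` must be named and cover every sample;
#'   they are written in `samples` order.
#' @param path Output file.
#' @param samples Optional sample-id vector fixing the output order.
#' @export
writeCls <- function(labels, path, samples = NULL) {
  if (!is.null(samples)) {
    if (is.null(names(labels)))
      stop("labels must be named when 'samples' is given", call. = FALSE)
    miss <- setdiff(samples, names(labels))
    if (length(miss))
      stop("no class label for sample(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    labels <- labels[samples]
  }
  lab <- as.character(labels)
  classes <- unique(lab)
  writeLines(c(paste(length(lab), length(classes), "1"),
               paste(c("#", classes), collapse = " "),
               paste(match(lab, classes) - 1L, collapse = " ")), path)
  invisible(path)
}

#' @rdname writeCls
#' @return `readCls` returns a factor of class labels in sample order,
#'   levels in declaration order.
#' @export
readCls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("not a CLS file: ", path, call. = FALSE)
  classes <- strsplit(sub("^#\\s*", "", lines[2]), "\\s+")[[1]]
  idx <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  factor(classes[idx + 1L], levels = classes)
}
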