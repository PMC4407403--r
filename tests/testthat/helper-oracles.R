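# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops over all pairs) so they cannot share a
# bug with the package's sweep/matrix-product implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Matrix)
  library(S4Vectors)
})

# All-pairs membership double loop over (gene, probe); coordinates are
# pulled into plain vectors up front, the loop itself stays scalar.
brute_base_matrix <- function(pg, probes, scheme) {
  n_g <- length(pg); n_p <- length(probes)
  g_chr <- as.character(seqnames(pg)); g_s <- start(pg); g_e <- end(pg)
  p_chr <- as.character(seqnames(probes))
  p_s <- start(probes); p_e <- end(probes)
  m <- matrix(0, n_g, n_p,
              dimnames = list(mcols(pg)$symbol, names(probes)))
  for (j in seq_len(n_g)) {
    for (i in seq_len(n_p)) {
      if (p_chr[i] == g_chr[j] && p_s[i] <= g_e[j] && p_e[i] >= g_s[j])
        m[j, i] <- 1
    }
  }
  if (scheme == "averaged") {
    for (j in seq_len(n_g)) {
      k <- sum(m[j, ])
      if (k > 0) m[j, ] <- m[j, ] / k
    }
  }
  m
}

# Explicit per-gene, per-sample accumulation over member probes.
brute_cnar <- function(membership, cna, scheme) {
  n_g <- nrow(membership); n_s <- ncol(cna)
  out <- matrix(NA_real_, n_g, n_s,
                dimnames = list(rownames(membership), colnames(cna)))
  for (j in seq_len(n_g)) {
    member <- which(membership[j, ] != 0)
    for (s in seq_len(n_s)) {
      v <- cna[member, s]
      v <- v[!is.na(v)]
      if (length(v) > 0)
        out[j, s] <- if (scheme == "binary") sum(v) else mean(v)
    }
  }
  out
}

# Rousseeuw silhouette from first principles, all pairwise distances.
brute_silhouette <- function(data, labels) {
  d <- as.matrix(stats::dist(data))
  n <- nrow(d)
  labels <- as.integer(factor(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Random pseudogene/probe layout (windows drawn directly, no extension).
random_layout <- function(n_genes, n_probes, seed,
                          n_chrom = 3, chrom_len = 1e6) {
  withr::with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    g_start <- floor(runif(n_genes, 1, chrom_len - 60000))
    pg <- GRanges(sample(chroms, n_genes, replace = TRUE),
                  IRanges(g_start,
                          g_start + floor(runif(n_genes, 1000, 60000))))
    mcols(pg)$symbol <- sprintf("G%03d", seq_len(n_genes))
    mcols(pg)$probe_count <- NA_integer_
    p_start <- floor(runif(n_probes, 1, chrom_len - 60))
    probes <- GRanges(sample(chroms, n_probes, replace = TRUE),
                      IRanges(p_start, p_start + 59))
    names(probes) <- sprintf("P%04d", seq_len(n_probes))
    list(pg = pg, probes = probes)
  })
}

random_cna <- function(n_probes, n_samples, seed, missing = 0) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_probes * n_samples), n_probes, n_samples,
                dimnames = list(sprintf("P%04d", seq_len(n_probes)),
                                sprintf("S%02d", seq_len(n_samples))))
    if (missing > 0) m[runif(length(m)) < missing] <- NA_real_
    m
  })
}

# Two well-separated Gaussian blobs: centres 'separation' times the
# radial within-cluster SD (sd * sqrt(p)) apart.
two_blobs <- function(n_per = 20, p = 5, separation = 20, sd = 1,
                      seed = 1) {
  withr::with_seed(seed, {
    shift <- separation * sd
    x <- rbind(matrix(rnorm(n_per * p, 0, sd), n_per),
               matrix(rnorm(n_per * p, shift, sd), n_per))
    rownames(x) <- sprintf("S%02d", seq_len(2 * n_per))
    list(data = x, labels = rep(1:2, each = n_per))
  })
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

tiny_sim_config <- function(...) {
  args <- utils::modifyList(
    list(nChromosomes = 2, chromosomeLength = 2e6, nGenes = 10,
         probeSpacing = 5500, nSamplesPerClass = 5, nDriverGenes = 2),
    list(...))
  do.call(simulationConfig, args)
}
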