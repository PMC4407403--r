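#' Simulation configuration for synthetic CNA cohorts
#'
#' Defines a two-class array-CGH cohort with known ground truth: a
#' multi-chromosome layout of genes and tiled 60 bp probes, and a set of
#' "driver" genes whose member probes carry a class-dependent mean shift in
#' log2 ratio over i.i.d. Gaussian probe noise.
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: 20 chromosomes of 20 Mb carrying 2,000 genes of
#' 5--20 kb (one gene per 200 kb on average); probes tiled every 5,500 bp
#' (about 72,700 probes, and about 37 member probes per extended gene
#' region under the default 100 kb flank + 2 kb promoter extension); 20
#' samples per class; 5 driver genes with a log2-ratio shift of 1.0
#' against probe noise SD 0.3; no missing values. Gene density matters:
#' pseudogene windows are ~212 kb wide, so at much higher densities
#' neighbouring genes share most of a driver's member probes and inherit
#' its class signal (as they do in real data).
#'
#' @param nChromosomes,chromosomeLength Genome layout (count, bp).
#' @param nGenes Number of genes (may be 0).
#' @param geneLengthRange Min/max gene length in bp.
#' @param probeLength,probeSpacing Probe tiling (bp).
#' @param nSamplesPerClass Samples in each of the two classes.
#' @param nDriverGenes Number of class-shifted genes.
#' @param driverShift Between-class mean log2-ratio difference at driver
#'   probes; drivers alternate gain (+) and loss (-).
#' @param noiseSd Per-probe Gaussian noise SD (log2-ratio units).
#' @param missingFraction Fraction of cells masked missing, in \[0, 1).
#' @param flank,promoter Pseudogene extension used when placing drivers.
#' @param classNames Two class labels (default short/long survival).
#' @param seed Default seed for [simulateAnnotation()]/[simulateCna()].
#' @return A validated configuration list (class `"SimulationConfig"`).
#' @export
simulationConfig <- function(nChromosomes = 20, chromosomeLength = 20e6,
                             nGenes = 2000,
                             geneLengthRange = c(5000, 20000),
                             probeLength = 60, probeSpacing = 5500,
                             nSamplesPerClass = 20, nDriverGenes = 5,
                             driverShift = 1.0, noiseSd = 0.3,
                             missingFraction = 0,
                             flank = 100000, promoter = 2000,
                             classNames = c("short", "long"), seed = 1) {
  cfg <- list(nChromosomes = as.integer(nChromosomes),
              chromosomeLength = as.numeric(chromosomeLength),
              nGenes = as.integer(nGenes),
              geneLengthRange = as.numeric(geneLengthRange),
              probeLength = as.integer(probeLength),
              probeSpacing = as.numeric(probeSpacing),
              nSamplesPerClass = as.integer(nSamplesPerClass),
              nDriverGenes = as.integer(nDriverGenes),
              driverShift = as.numeric(driverShift),
              noiseSd = as.numeric(noiseSd),
              missingFraction = as.numeric(missingFraction),
              flank = as.numeric(flank), promoter = as.numeric(promoter),
              classNames = as.character(classNames),
              seed = as.integer(seed))
  stopifnot(cfg$nChromosomes >= 1, cfg$chromosomeLength >= 1,
            cfg$nGenes >= 0, length(cfg$geneLengthRange) == 2,
            cfg$geneLengthRange[1] >= 1,
            cfg$geneLengthRange[2] >= cfg$geneLengthRange[1],
            cfg$probeLength >= 1, cfg$probeSpacing >= 1,
            cfg$nSamplesPerClass >= 1, cfg$nDriverGenes >= 0,
            cfg$noiseSd >= 0,
            cfg$missingFraction >= 0, cfg$missingFraction < 1,
            length(cfg$classNames) == 2)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate gene and probe annotation tables
#'
#' Genes are placed uniformly per chromosome (overlap permitted, as in real
#' annotations); probes are tiled at fixed spacing along every chromosome.
#' Deterministic given the seed.
#'
#' @param config A [simulationConfig()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `genes` (`GRanges` with `symbol`, strand), `probes`
#'   (named `GRanges`) and `chromosomeLengths` (named vector).
#' @export
simulateAnnotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  L <- config$chromosomeLength
  if (config$geneLengthRange[2] > L)
    stop("gene length exceeds chromosome length", call. = FALSE)
  chroms <- paste0("chr", seq_len(config$nChromosomes))
  chrom_len <- stats::setNames(rep(L, length(chroms)), chroms)

  withr::with_seed(as.integer(seed), {
    if (config$nGenes > 0) {
      g_chr <- sample(chroms, config$nGenes, replace = TRUE)
      g_len <- floor(stats::runif(config$nGenes,
                                  config$geneLengthRange[1],
                                  config$geneLengthRange[2] + 1))
      g_start <- floor(stats::runif(config$nGenes, 1, L - g_len + 1))
      g_strand <- sample(c("+", "-"), config$nGenes, replace = TRUE)
      genes <- GRanges(g_chr, IRanges(g_start, g_start + g_len - 1),
                       strand = g_strand,
                       symbol = sprintf("GENE%05d",
                                        seq_len(config$nGenes)))
    } else {
      genes <- GRanges()
      mcols(genes)$symbol <- character(0)
    }
  })

  p_start <- seq(1, L - config$probeLength + 1, by = config$probeSpacing)
  probes <- GRanges(rep(chroms, each = length(p_start)),
                    IRanges(rep(p_start, length(chroms)),
                            width = config$probeLength))
  names(probes) <- sprintf("PROBE%07d", seq_along(probes))
  list(genes = genes, probes = probes, chromosomeLengths = chrom_len)
}

#' Simulate a class-structured CNA matrix with known drivers
#'
#' Builds the pseudogene extension of the simulated genes, draws
#' `nDriverGenes` drivers (without replacement) from genes with at least
#' one member probe, and generates probe-level log2 ratios: the first class
#' is copy-neutral (mean 0 everywhere); in the second class every member
#' probe of a driver pseudogene inherits the driver's mean (+`driverShift`
#' for odd-numbered drivers, -`driverShift` for even, i.e. alternating gain
#' and loss; a probe covered by several drivers takes the first drawn).
#' Gaussian noise of SD `noiseSd` is added everywhere and a
#' `missingFraction` of cells is masked uniformly at random. Deterministic
#' given the seed.
#'
#' @param annotation Output of [simulateAnnotation()].
#' @param config The same [simulationConfig()].
#' @param seed Seed (defaults to `config$seed`); vary it to draw replicate
#'   cohorts on a fixed annotation.
#' @return List: `cna` (probes x samples matrix), `labels` (named factor),
#'   `truth` (`DataFrame`: driver `symbol`, per-class true means),
#'   `annotation` (a [CnaAnnotation-class] with `probe_count` filled).
#' @export
simulateCna <- function(annotation, config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  pg <- extendGenes(annotation$genes, flank = config$flank,
                    promoter = config$promoter,
                    chromosomeLengths = annotation$chromosomeLengths)
  ann <- CnaAnnotation(pg, annotation$probes)
  hits <- findOverlaps(annotation$probes, pg, ignore.strand = TRUE)
  k <- tabulate(S4Vectors::subjectHits(hits), length(pg))
  mcols(pg)$probe_count <- as.integer(k)
  ann <- CnaAnnotation(pg, annotation$probes)

  eligible <- mcols(pg)$symbol[k >= 1]
  if (config$nDriverGenes > length(eligible))
    stop("nDriverGenes exceeds the ", length(eligible),
         " genes with at least one member probe", call. = FALSE)

  n_p <- length(annotation$probes)
  n_per <- config$nSamplesPerClass
  n_s <- 2L * n_per
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  labels <- factor(rep(config$classNames, each = n_per),
                   levels = config$classNames)
  names(labels) <- sample_ids

  withr::with_seed(as.integer(seed), {
    drivers <- if (config$nDriverGenes > 0)
      sample(eligible, config$nDriverGenes) else character(0)
    driver_mean <- ifelse(seq_along(drivers) %% 2 == 1,
                          config$driverShift, -config$driverShift)
    # per-probe mean in the shifted (second) class; first driver drawn wins
    probe_mean <- rep(0, n_p)
    assigned <- logical(n_p)
    pg_sym <- mcols(pg)$symbol
    for (d in seq_along(drivers)) {
      j <- match(drivers[d], pg_sym)
      member <- S4Vectors::queryHits(hits)[
        S4Vectors::subjectHits(hits) == j]
      take <- member[!assigned[member]]
      probe_mean[take] <- driver_mean[d]
      assigned[take] <- TRUE
    }
    mu <- cbind(matrix(0, n_p, n_per),
                matrix(probe_mean, n_p, n_per))
    cna <- mu + matrix(stats::rnorm(n_p * n_s, 0, config$noiseSd),
                       n_p, n_s)
    if (config$missingFraction > 0)
      cna[stats::runif(n_p * n_s) < config$missingFraction] <- NA_real_
  })
  dimnames(cna) <- list(names(annotation$probes), sample_ids)

  truth <- DataFrame(symbol = drivers,
                     mean_A = rep(0, length(drivers)),
                     mean_B = driver_mean)
  S4Vectors::metadata(truth)$classes <- config$classNames
  list(cna = cna, labels = labels, truth = truth, annotation = ann)
}
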