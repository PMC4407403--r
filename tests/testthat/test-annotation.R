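test_that("gene annotation parses in file order, skips malformed rows, and
           defaults unknown strand", {
  df <- data.frame(symbol = c("A", "B", "C"), chrom = "chr1",
                   start = c(100, 200, 300), end = c(150, 250, 350),
                   strand = c("+", "-", "+"))
  g <- readGeneAnnotation(write_tsv(df))
  expect_equal(mcols(g)$symbol, c("A", "B", "C"))
  expect_equal(start(g), c(100, 200, 300))

  bad <- df
  bad$end[2] <- 100  # end < start
  expect_message(g2 <- readGeneAnnotation(write_tsv(bad)),
                 "skipped 1 row")
  expect_equal(mcols(g2)$symbol, c("A", "C"))

  df5 <- data.frame(symbol = paste0("G", 1:5), chrom = "chr2",
                    start = 1:5 * 100, end = 1:5 * 100 + 50,
                    strand = c("+", "", "-", "+", "+"))
  g5 <- readGeneAnnotation(write_tsv(df5))
  expect_length(g5, 5)
  expect_equal(as.character(strand(g5))[2], "*")
})

test_that("gene annotation fatal errors: missing file, unmappable columns,
           zero valid rows", {
  expect_error(readGeneAnnotation(tempfile()), "not found")
  junk <- write_tsv(data.frame(a = 1, b = 2))
  expect_error(readGeneAnnotation(junk), "cannot map")
  allbad <- write_tsv(data.frame(symbol = "A", chrom = "chr1",
                                 start = 10, end = 5, strand = "+"))
  expect_error(suppressMessages(readGeneAnnotation(allbad)),
               "no valid rows")
})

test_that("probe annotation enforces unique ids (keep first, warn; fatal
           beyond threshold) and accepts 1 bp probes", {
  df <- data.frame(probe_id = paste0("P", 1:10), chrom = "chr1",
                   start = 1:10 * 100, end = 1:10 * 100 + 59)
  p <- readProbeAnnotation(write_tsv(df))
  expect_length(p, 10)
  expect_equal(names(p), paste0("P", 1:10))

  dup <- rbind(df, df[1, ])
  dup$start[11] <- 5000
  dup$end[11] <- 5059
  expect_warning(p2 <- readProbeAnnotation(write_tsv(dup),
                                           maxDuplicateFraction = 0.5),
                 "duplicate")
  expect_length(p2, 10)
  expect_equal(start(p2)[1], 100)  # first kept

  expect_error(
    suppressWarnings(readProbeAnnotation(write_tsv(dup),
                                         maxDuplicateFraction = 0.01)),
    "exceeds")

  one_bp <- write_tsv(data.frame(probe_id = "P1", chrom = "chr1",
                                 start = 500, end = 500))
  expect_equal(width(readProbeAnnotation(one_bp)), 1)
})

test_that("gene deduplication keeps the longest span with deterministic
           tie-breaks and is idempotent", {
  g <- GRanges(c("chr1", "chr1", "chr1"),
               IRanges(c(100, 500, 100), width = c(10000, 5000, 20000)),
               symbol = c("A", "B", "A"))
  expect_message(d <- deduplicateGenes(g), "dropped 1")
  expect_equal(mcols(d)$symbol, c("B", "A"))
  expect_equal(width(d[mcols(d)$symbol == "A"]), 20000)

  # equal spans: smallest start wins
  tie <- GRanges("chr1", IRanges(c(100, 50), width = 1000),
                 symbol = c("A", "A"))
  expect_message(dt <- deduplicateGenes(tie))
  expect_equal(start(dt), 50)

  # already-unique input passes through untouched, in order
  u <- GRanges("chr1", IRanges(c(5, 1), width = 10),
               symbol = c("X", "Y"))
  expect_identical(deduplicateGenes(u), u)
  expect_identical(suppressMessages(deduplicateGenes(d)), d)
})

test_that("pseudogene extension applies flank plus strand-aware promoter
           and clamps at chromosome bounds", {
  g <- GRanges("chr1", IRanges(500000, 510000), strand = "+",
               symbol = "G1")
  pg <- extendGenes(g)
  expect_equal(start(pg), 398000)
  expect_equal(end(pg), 610000)

  strand(g) <- "-"
  pg <- extendGenes(g)
  expect_equal(start(pg), 400000)
  expect_equal(end(pg), 612000)

  near <- GRanges("chr1", IRanges(50000, 60000), strand = "+",
                  symbol = "G2")
  pg <- extendGenes(near)
  expect_equal(start(pg), 1)
  expect_equal(end(pg), 160000)

  pg <- extendGenes(near, chromosomeLengths = c(chr1 = 120000))
  expect_equal(end(pg), 120000)

  # unknown strand or symmetric mode: promoter on both sides
  strand(near) <- "*"
  pg <- extendGenes(near)
  expect_equal(c(start(pg), end(pg)), c(1, 162000))
  strand(near) <- "+"
  pg <- extendGenes(near, strandAwarePromoter = FALSE)
  expect_equal(c(start(pg), end(pg)), c(1, 162000))
})

test_that("extension invariants hold on random genes: containment and the
           length bound 2*flank + promoter", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 50
      g <- GRanges(sample(paste0("chr", 1:3), n, replace = TRUE),
                   IRanges(floor(runif(n, 1, 5e6)),
                           width = floor(runif(n, 100, 50000))),
                   strand = sample(c("+", "-", "*"), n, replace = TRUE),
                   symbol = sprintf("G%02d", 1:n))
      pg <- extendGenes(g, flank = 10000, promoter = 500)
      expect_true(all(start(pg) <= start(g) & end(pg) >= end(g)))
      extra <- width(pg) - width(g)
      limit <- 2 * 10000 + 500 * ifelse(as.character(strand(g)) == "*",
                                        2, 1)
      expect_true(all(extra <= limit))
      unclamped <- start(g) - 10000 - 500 >= 1
      plus <- as.character(strand(g)) == "+"
      expect_true(all(extra[unclamped & plus] == (2 * 10000 + 500)))
    }
  })
})

test_that("annotation tables round-trip through their TSV serializers", {
  cfg <- tiny_sim_config()
  ann <- simulateAnnotation(cfg)
  gf <- tempfile(fileext = ".tsv"); pf <- tempfile(fileext = ".tsv")
  writeGeneAnnotation(ann$genes, gf)
  writeProbeAnnotation(ann$probes, pf)
  g2 <- readGeneAnnotation(gf)
  p2 <- readProbeAnnotation(pf)
  expect_equal(mcols(g2)$symbol, mcols(ann$genes)$symbol)
  expect_equal(start(g2), start(ann$genes))
  expect_equal(as.character(strand(g2)), as.character(strand(ann$genes)))
  expect_equal(names(p2), names(ann$probes))
  expect_equal(start(p2), start(ann$probes))
  # and a second round trip is byte-identical
  gf2 <- tempfile(); writeGeneAnnotation(g2, gf2)
  expect_identical(readLines(gf), readLines(gf2))
})
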