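make_cna_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("CNA matrix reader handles gaps, and rejects duplicate ids and
           ragged rows with the offending row number", {
  path <- make_cna_file(c("probe_id\ts1\ts2",
                          "P1\t0.1\t0.2", "P2\t-0.3\t0.4",
                          "P3\t0\t1", "P4\t2\t-2"))
  m <- readCnaMatrix(path)
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(m["P2", "s2"], 0.4)

  gap <- make_cna_file(c("probe_id\ts1\ts2",
                         "P1\t0.1\tNA", "P2\t-0.3\t0.4",
                         "P3\t0\t1", "P4\t2\t-2"))
  mg <- suppressMessages(readCnaMatrix(gap))
  expect_true(is.na(mg["P1", "s2"]))
  expect_equal(mean(is.na(mg)), 1 / 8)

  ragged <- make_cna_file(c("probe_id\ts1\ts2",
                            "P1\t0.1\t0.2", "P2\t-0.3"))
  expect_error(readCnaMatrix(ragged), "row 3")

  dup_s <- make_cna_file(c("probe_id\ts1\ts1", "P1\t0.1\t0.2"))
  expect_error(readCnaMatrix(dup_s), "duplicate sample")
  dup_p <- make_cna_file(c("probe_id\ts1", "P1\t0.1", "P1\t0.2"))
  expect_error(readCnaMatrix(dup_p), "duplicate probe")
})

two_probe_fixture <- function(scheme) {
  pg <- GRanges("chr1", IRanges(1000, 3000), symbol = "G1",
                probe_count = NA_integer_)
  probes <- GRanges("chr1", IRanges(c(1200, 1800), width = 60))
  names(probes) <- c("P1", "P2")
  buildBaseMatrix(CnaAnnotation(pg, probes), scheme)
}

test_that("gene value is the mean (averaged) or sum (binary) of member
           probes", {
  cna <- matrix(c(0.2, 0.4), 2, 1,
                dimnames = list(c("P1", "P2"), "s1"))
  expect_equal(cnarValues(generateCnar(two_probe_fixture("averaged"),
                                       cna))["G1", "s1"], 0.3)
  expect_equal(cnarValues(generateCnar(two_probe_fixture("binary"),
                                       cna))["G1", "s1"], 0.6)
})

test_that("missing probes renormalize averaged weights over observed
           members; all-missing and zero-probe genes give NA", {
  bm <- two_probe_fixture("averaged")
  cna <- matrix(c(0.2, NA, NA, NA), 2, 2,
                dimnames = list(c("P1", "P2"), c("s1", "s2")))
  v <- cnarValues(generateCnar(bm, cna))
  expect_equal(v["G1", "s1"], 0.2)   # mean of the one observed member
  expect_true(is.na(v["G1", "s2"]))  # all members missing
})

test_that("matrix-product CNAR equals the explicit per-gene accumulation
           loop on random instances, with and without missing data", {
  for (s in 1:5) {
    lay <- random_layout(30, 200, seed = 300 + s)
    ann <- CnaAnnotation(lay$pg, lay$probes)
    cna <- random_cna(200, 5, seed = 400 + s,
                      missing = ifelse(s > 3, 0.2, 0))
    for (scheme in c("binary", "averaged")) {
      bm <- buildBaseMatrix(ann, scheme)
      got <- cnarValues(generateCnar(bm, cna))
      oracle <- brute_cnar(as.matrix(baseWeights(bm)), cna, scheme)
      expect_equal(is.na(got), is.na(oracle))
      expect_lt(max(abs(got - oracle), na.rm = TRUE), 1e-12)
    }
  }
})

test_that("probe reconciliation drops unshared ids with a message and an
           empty intersection is fatal", {
  bm <- two_probe_fixture("averaged")
  cna <- matrix(c(0.2, 0.4, 9), 3, 1,
                dimnames = list(c("P1", "P2", "P_other"), "s1"))
  expect_message(x <- generateCnar(bm, cna), "dropped")
  expect_equal(cnarValues(x)["G1", "s1"], 0.3)
  bad <- matrix(1, 1, 1, dimnames = list("Q1", "s1"))
  expect_error(generateCnar(bm, bad), "no probe ids shared")
})

test_that("CNAR transform is linear and column-permutation equivariant,
           and averaged values stay within member-probe range", {
  lay <- random_layout(20, 150, seed = 9)
  ann <- CnaAnnotation(lay$pg, lay$probes)
  bm <- buildBaseMatrix(ann, "averaged")
  d1 <- random_cna(150, 4, seed = 21)
  d2 <- random_cna(150, 4, seed = 22)
  lin <- cnarValues(generateCnar(bm, 2 * d1 - 0.5 * d2))
  parts <- 2 * cnarValues(generateCnar(bm, d1)) -
    0.5 * cnarValues(generateCnar(bm, d2))
  expect_equal(lin, parts, tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  expect_equal(cnarValues(generateCnar(bm, d1[, perm])),
               cnarValues(generateCnar(bm, d1))[, perm])

  v <- cnarValues(generateCnar(bm, d1))
  member <- as.matrix(baseWeights(bm)) != 0
  for (j in which(rowSums(member) > 0)) {
    rng <- range(d1[member[j, ], ])
    expect_true(all(v[j, ] >= rng[1] - 1e-12 & v[j, ] <= rng[2] + 1e-12))
  }
})

test_that("variance filter keeps genes with sample variance strictly above
           the cutoff and counts degenerate genes separately", {
  m <- rbind(const = c(1, 1, 1),
             spread = c(0, 1, 2),        # var 1.0
             mild = c(0, 0.5, 1),        # var 0.25
             degen = c(5, NA, NA))
  colnames(m) <- paste0("s", 1:3)
  f <- suppressMessages(varianceFilter(m, cutoff = 0.4))
  expect_equal(rownames(f), "spread")
  rep <- attr(f, "varianceFilter")
  expect_equal(rep$degenerate, 1)
  expect_equal(rep$belowCutoff, 2)

  f0 <- suppressMessages(varianceFilter(m, cutoff = 0))
  expect_setequal(rownames(f0), c("spread", "mild"))

  fsd <- suppressMessages(varianceFilter(m, cutoff = 0.4,
                                         statistic = "sd"))
  expect_setequal(rownames(fsd), c("spread", "mild"))  # sd 1.0 and 0.5
})

test_that("GCT layout is to spec and write-then-read reproduces the matrix
           exactly", {
  m <- matrix(c(0.123456789012345, -1.5, 2/3, 0, 1e-7, 42), 2, 3,
              dimnames = list(c("G1", "G2"), c("s1", "s2", "s3")))
  path <- tempfile(fileext = ".gct")
  writeGct(m, path)
  lines <- readLines(path)
  expect_equal(lines[1], "#1.2")
  expect_equal(lines[2], "2\t3")
  expect_equal(strsplit(lines[3], "\t")[[1]],
               c("NAME", "Description", "s1", "s2", "s3"))
  expect_identical(readGct(path), m)

  m[1, 2] <- NA
  writeGct(m, path)
  expect_identical(readGct(path), m)
})

test_that("CLS encodes classes in first-seen order and round-trips", {
  path <- tempfile(fileext = ".cls")
  labels <- c(s1 = "short", s2 = "long", s3 = "short")
  writeCls(labels, path, samples = c("s1", "s2", "s3"))
  lines <- readLines(path)
  expect_equal(lines[1], "3 2 1")
  expect_equal(lines[2], "# short long")
  expect_equal(lines[3], "0 1 0")
  expect_equal(as.character(readCls(path)), unname(labels))
  expect_equal(levels(readCls(path)), c("short", "long"))

  expect_error(writeCls(labels, path, samples = c("s1", "s4")), "s4")
})
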