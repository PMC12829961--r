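# Parsing, filtering, strand orientation and coverage reduction.

test_that("pairs-format parsing preserves records and validates chromosomes", {
  tf <- withr::local_tempfile()
  writeLines(c(
    "## pairs format v1.0",
    "#chromsize: chrA 100000",
    "#chromsize: chrB 50000",
    "r1\tchrA\t100\tchrA\t5000\t+\t-",
    "r2\tchrA\t200\tchrB\t300\t+\t+",
    "r3\tchrB\t10\tchrB\t4000\t-\t-"), tf)
  cp <- parseContacts(tf)
  expect_s4_class(cp, "ContactPairs")
  expect_equal(length(cp), 3L)
  expect_equal(chromSizes(cp), c(chrA = 100000, chrB = 50000))

  writeLines(c("#chromsize: chrA 100000",
               "r1\tchrX\t100\tchrA\t5000\t+\t-"), tf)
  expect_error(parseContacts(tf), "chrX")

  writeLines(c("## pairs format v1.0", "#chromsize: chrA 100000"), tf)
  expect_equal(length(parseContacts(tf)), 0L)
})

test_that("malformed lines are reported with their line number", {
  tf <- withr::local_tempfile()
  writeLines(c("## pairs format v1.0", "#chromsize: chrA 100000",
               "r1\tchrA\t100\tchrA\t5000\t+\t-",
               "r2\tchrA\t100"), tf)
  expect_error(parseContacts(tf), "line 4")
  writeLines(c("chrA\t100\t+\tXYZ\t-"), tf)
  expect_error(parseContacts(tf, format = "table",
                             chromSizes = c(chrA = 1e5)), "line 1")
})

test_that("table format reads positions, strands and optional mapq", {
  tf <- withr::local_tempfile()
  writeLines(c("chrA\t100\t+\t5000\t-\t12",
               "chrA\t200\t+\t7000\t-"), tf)
  cp <- parseContacts(tf, format = "table", chromSizes = c(chrA = 1e5))
  expect_equal(length(cp), 2L)
  expect_equal(pairsTable(cp)$mapq1, c(12, NA))
})

test_that("insert-length and chromosome filters follow the printed windows", {
  rl <- 50
  # inserts: |pos2 - pos1| + readLength
  cp <- makePairs(pos1 = c(0, 0, 0, 0), pos2 = c(449, 450, 4999950, 4999951),
                  len = 6e6)
  f <- filterPairs(cp)
  ins <- abs(pairsTable(f)$pos2 - pairsTable(f)$pos1) + rl
  expect_equal(ins, c(500, 5e6))   # 499 dropped, 500 kept (inclusive), 5 Mb kept

  inter <- makePairs(pos1 = 100, pos2 = 5000, chrom = "chrA", chrom2 = "chrB")
  expect_equal(length(filterPairs(inter)), 0L)
})

test_that("mapq gating, dedup and idempotence", {
  cp <- makePairs(pos1 = c(0, 0, 0), pos2 = c(1000, 1000, 2000),
                  mapq = c(29, 60, NA))
  f <- filterPairs(cp)
  expect_equal(nrow(pairsTable(f)), 2L)   # mapq 29 dropped, NA passes
  f2 <- filterPairs(filterPairs(cp))
  expect_equal(pairsTable(f2), pairsTable(f))
  d <- filterPairs(makePairs(pos1 = c(0, 0), pos2 = c(1000, 1000)),
                   dedup = TRUE)
  expect_equal(length(d), 1L)
})

test_that("orientation splits by linear order and coverage is additive", {
  cp <- filterPairs(makePairs(pos1 = 100, pos2 = 5100, len = 10000))
  cov <- orientAndCoverage(cp, "chrT")
  d5 <- as.integer(cov$five_prime@depth)
  d3 <- as.integer(cov$three_prime@depth)
  expect_equal(which(d5 == 1) - 1L, 100:149)
  expect_equal(which(d3 == 1) - 1L, 5100:5149)

  # reversed input order: upstream read still decides the five_prime group
  cpRev <- filterPairs(makePairs(pos1 = 5100, pos2 = 100, len = 10000))
  covRev <- orientAndCoverage(cpRev, "chrT")
  expect_equal(as.integer(covRev$five_prime@depth), d5)

  two <- filterPairs(makePairs(pos1 = c(100, 100), pos2 = c(5100, 5100),
                               len = 10000))
  cov2 <- orientAndCoverage(two, "chrT")
  expect_equal(as.integer(cov2$five_prime@depth), 2L * d5)

  expect_error(orientAndCoverage(cp, "chrZ"), "chrZ")
})

test_that("coverage conserves the aligned bases of retained pairs", {
  set.seed(1)
  cp <- filterPairs(makePairs(pos1 = sample(1e5, 50),
                              pos2 = sample(1e5, 50) + 2e5, len = 1e6))
  cov <- orientAndCoverage(cp, "chrT")
  tot <- sum(as.numeric(S4Vectors::runValue(cov$five_prime@depth) *
                          S4Vectors::runLength(cov$five_prime@depth))) +
    sum(as.numeric(S4Vectors::runValue(cov$three_prime@depth) *
                     S4Vectors::runLength(cov$three_prime@depth)))
  expect_equal(tot, length(cp) * 2 * readLength(cp))
})

test_that("compressLog removes zeros and natural-log transforms", {
  tr <- asTrack(c(0, 0, 2, 3, 0, 1))
  cs <- compressLog(tr)
  expect_equal(signalValues(cs), c(log(2), log(3), 0))
  expect_equal(indexMap(cs), c(2, 3, 5))

  ones <- compressLog(asTrack(rep(1, 10)))
  expect_equal(signalValues(ones), rep(0, 10))
  expect_equal(indexMap(ones), 0:9)

  expect_length(signalValues(compressLog(asTrack(rep(0, 10)))), 0L)
})

test_that("compress/decompress round-trips the log coverage", {
  set.seed(2)
  depth <- rpois(500, 0.8)
  cs <- compressLog(asTrack(depth))
  rebuilt <- rep(NA_real_, 500)
  rebuilt[indexMap(cs) + 1] <- signalValues(cs)
  expect_equal(rebuilt[depth > 0], log(depth[depth > 0]))
  expect_true(all(is.na(rebuilt[depth == 0])))
  expect_true(all(diff(indexMap(cs)) > 0))
})
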