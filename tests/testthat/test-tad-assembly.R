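# Boundary pairing, diamond refinement, scoring, TSV round trip.

makeBoundarySet <- function(pos, side, p = 1e-4, scale = 8L,
                            support = 5000) {
  GenomicRanges::GRanges(
    seqnames = rep("chrT", length(pos)),
    ranges = IRanges::IRanges(start = pos + 1, width = 1),
    side = rep(side, length(pos)),
    scale = rep(scale, length.out = length(pos)),
    p_adj = rep(p, length.out = length(pos)),
    support = rep(support, length.out = length(pos)))
}

test_that("pairing respects the size window and multiplies probabilities", {
  left <- makeBoundarySet(1e5, "left", p = 0.01)
  right <- makeBoundarySet(c(1.2e5, 1.4e5, 3e5, 5.2e6 + 1e5), "right",
                           p = 0.02)
  cands <- pairBoundaries(left, right)
  # 20 kb span and > 5 Mb span excluded; 40 kb span inclusive
  expect_equal(cands$end, c(1.4e5, 3e5))
  expect_equal(cands$pairP, rep(0.01 * 0.02, 2))

  none <- pairBoundaries(left, makeBoundarySet(numeric(0), "right"))
  expect_equal(nrow(none), 0L)
})

test_that("pair candidates are sorted and capped by pair probability", {
  left <- makeBoundarySet(c(2e5, 1e5), "left", p = c(0.04, 0.01))
  right <- makeBoundarySet(c(4e5, 3e5), "right", p = c(0.03, 0.02))
  cands <- pairBoundaries(left, right)
  expect_equal(cands$start, c(1e5, 1e5, 2e5, 2e5))
  expect_true(!is.unsorted(cands$end[cands$start == 1e5]))
  expect_message(capped <- pairBoundaries(left, right, cap = 2), "cap")
  expect_equal(nrow(capped), 2L)
  expect_true(all(capped$pairP <= sort(cands$pairP)[2]))
})

test_that("diamond refinement collapses a flanking pair onto the planted step", {
  # block contact structure with a boundary between bins 19|20
  n <- 40
  res <- 1000
  M <- matrix(2, n, n)
  M[1:20, 1:20] <- 12
  M[21:n, 21:n] <- 12
  set.seed(50)
  M <- M + matrix(rpois(n * n, 1), n, n)
  M <- (M + t(M)) / 2
  cm <- new("ContactMatrix", chrom = "chrT", resolution = res,
            counts = methods::as(Matrix::triu(Matrix::Matrix(M, sparse = TRUE)),
                                 "CsparseMatrix"),
            weights = rep(1, n), chromLength = n * res, balanced = TRUE)
  # two near-duplicate left calls 2 kb apart flanking the 20 kb step,
  # paired with the same right boundary
  cands <- data.frame(
    chrom = "chrT", start = c(19000, 21000), end = c(39000, 39000),
    Lp = c(1e-6, 1e-8), Rp = 1e-6, pairP = c(1e-12, 1e-14),
    leftScale = c(8L, 9L), rightScale = 8L,
    leftSupport = 5000, rightSupport = 5000,
    ANCp = 1e-4, anchorRes = res)
  ref <- diamondRefine(cands, list(cm), w = 5)
  expect_equal(nrow(ref), 1L)
  expect_true(floor(ref$start / res) %in% c(19, 20))
  expect_equal(ref$refineResLeft, res)

  # isolated boundary: no neighbour within the radius -> unchanged
  iso <- cands[1, ]
  iso$start <- 5000
  refIso <- diamondRefine(iso, list(cm), w = 5)
  expect_equal(refIso$start, 5000)
  expect_true(is.na(refIso$refineResLeft))
})

test_that("scores multiply components and keep the hierarchy", {
  cands <- data.frame(chrom = "chrT", start = c(0, 1e5), end = c(4e5, 3e5),
                      Lp = c(0.1, 0.2), Rp = c(0.1, 0.3),
                      pairP = c(0.01, 0.06), leftScale = 8L, rightScale = 8L,
                      leftSupport = 1, rightSupport = 1,
                      ANCp = c(0.1, 1), anchorRes = 5000)
  tads <- scoreTADs(cands)
  m <- S4Vectors::mcols(tads)
  expect_equal(m$TADp, m$Lp * m$Rp * m$ANCp)
  expect_equal(m$TADp[m$ANCp == 1], (0.2 * 0.3))   # neutral anchor factor
  expect_equal(m$negLog10TADp[m$Lp == 0.1], 3, tolerance = 1e-12)
  expect_length(tads, 2L)                           # overlapping calls kept
  expect_true(all(m$TADp <= pmin(m$Lp, m$Rp, m$ANCp)))
  expect_true(all(m$TADp > 0))
})

test_that("calls round-trip through the TSV at 12 significant digits", {
  set.seed(51)
  n <- 100
  Lp <- runif(n) * 1e-3
  Rp <- runif(n) * 1e-2
  ANCp <- runif(n)
  cands <- data.frame(chrom = "chrT", start = sort(sample(1e6, n)) * 1.0,
                      end = 0, Lp = Lp, Rp = Rp, pairP = Lp * Rp,
                      leftScale = 8L, rightScale = 8L, leftSupport = 1,
                      rightSupport = 1, ANCp = ANCp, anchorRes = 5000)
  cands$end <- cands$start + 5e4
  tads <- scoreTADs(cands)
  tf <- withr::local_tempfile()
  writeCalls(tads, tf)
  back <- readCalls(tf)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(tads))
  for (col in c("Lp", "Rp", "ANCp", "TADp"))
    expect_equal(S4Vectors::mcols(back)[[col]], S4Vectors::mcols(tads)[[col]],
                 tolerance = 1e-11)

  empty <- scoreTADs(cands[0, ])
  writeCalls(empty, tf)
  expect_equal(length(readCalls(tf)), 0L)
  expect_equal(readLines(tf),
               "chrom\tstart\tend\tLp\tRp\tANCp\tTADp\tneg_log10_TADp")

  writeLines(c("chrom\tstart\tend\tLp\tRp\tANCp\tTADp\tneg_log10_TADp",
               "chrT\t0\t50000\t0.1\t0.1\tnot-a-number\t0.001\t3"), tf)
  expect_error(readCalls(tf), "line 2")
})
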