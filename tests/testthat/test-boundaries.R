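# Wavelet-variance null, coefficient p-values, run merging.

# a decomposition with prescribed per-scale coefficients
fakeDecomp <- function(details) {
  n <- length(details[[1L]])
  new("WaveletDecomposition", signal = asSignal(numeric(n)),
      details = details, smooth = numeric(n), J = length(details),
      filterName = "c6")
}

test_that("cascade null halves per scale from scale 1, lagged once", {
  d <- fakeDecomp(list(c(-2, 0, 2), c(0, 0, 0), c(0, 0, 0)))  # var = 4
  nl <- scaleNull(d, method = "cascade")
  expect_equal(nl$sigma2_1, 4)
  expect_equal(nl$sigma2_null, c(4, 4, 2))   # scale 3: 4 / 2^(3-2)

  expect_error(scaleNull(fakeDecomp(list(c(1, 1, 1)))), "degenerate")
})

test_that("empirical null uses the previous scale's variance, floored at own", {
  w1 <- c(-2, 0, 2)                 # var 4
  w2 <- c(-1, 0, 1)                 # var 1
  w3 <- c(-3, 0, 3)                 # var 9 (> previous: floor engages)
  nl <- scaleNull(fakeDecomp(list(w1, w2, w3)), method = "empirical")
  expect_equal(nl$sigma2_null, c(4, 4, 9))
})

test_that("white-noise variance halves per scale within sampling error", {
  set.seed(20)
  d <- modwtDetail(rnorm(65536), J = 4)
  v <- vapply(1:4, function(j) var(detailCoefficients(d, j)), 1)
  expect_gt(v[1] / v[2], 1.8)
  expect_lt(v[1] / v[2], 2.2)
  # sigma2_1 / 2^(j-1) tracks the empirical variance for j <= 4
  for (j in 2:4)
    expect_equal(v[j], v[1] / 2^(j - 1), tolerance = 0.15)
})

test_that("coefficient p-values follow the standard-normal upper tail", {
  s <- waveTAD:::.stepSign()
  w <- s * c(0, 2.326348, -1, 10)
  d <- fakeDecomp(list(w))
  nl <- list(sigma2_1 = 1, sigma2_null = 1)
  pv <- coefficientPvalues(d, nl, align = FALSE)
  expect_equal(pv$raw[[1]][1], 0.5)
  expect_equal(pv$raw[[1]][2], 0.01, tolerance = 1e-4)
  expect_gt(pv$raw[[1]][3], 0.5)
  expect_true(all(pv$adjusted[[1]] >= pv$raw[[1]]))
})

test_that("significant runs collapse to their mean genomic position", {
  n <- 40
  adj <- rep(1, n)
  adj[c(11, 12, 13)] <- 0.01      # one run (0-based genomic 1010..1012)
  sig <- new("CompressedSignal", values = rnorm(n),
             indexMap = as.numeric(1000 + 0:(n - 1)), chrom = "chrT",
             orientation = "five_prime")
  pv <- list(adjusted = list(adj), scales = 1L)
  b <- callBoundaries(pv, sig, side = "left")
  expect_equal(GenomicRanges::start(b) - 1, 1011)
  expect_equal(S4Vectors::mcols(b)$p_adj, 0.01)

  adj2 <- rep(1, n)
  adj2[c(11, 12, 14, 15)] <- 0.02  # two runs split by one miss
  b2 <- callBoundaries(list(adjusted = list(adj2), scales = 1L), sig,
                       side = "left")
  expect_length(b2, 2L)

  b0 <- callBoundaries(list(adjusted = list(rep(1, n)), scales = 1L), sig,
                       side = "left")
  expect_length(b0, 0L)
})

test_that("pure-noise coverage yields boundary calls at the FWER level", {
  set.seed(30)
  nCalls <- 0L
  nSignals <- 8L
  fracSig <- numeric(0)
  for (k in seq_len(nSignals)) {
    depth <- rpois(2^15, 5)
    depth[depth == 0] <- 1         # keep the index map dense and iid
    s <- compressLog(asTrack(depth))
    b <- trackBoundaries(s, minSupport = 1)
    nCalls <- nCalls + as.integer(length(b) > 0)
    dec <- modwtDetail(s, J = chooseMaxScale(s))
    pv <- coefficientPvalues(dec, scaleNull(dec, method = "empirical"))
    fracSig <- c(fracSig, mean(unlist(pv$adjusted) <= 0.05))
  }
  # FWER 0.05: expected signals with any call 0.4, allow 3 binomial SE
  expect_lte(nCalls, ceiling(0.05 * nSignals +
                               3 * sqrt(nSignals * 0.05 * 0.95)))
  expect_lt(max(fracSig), 0.05 + 3 * sqrt(0.05 * 0.95 / 2^15))
})

test_that("a low-to-high step is detected at the step location", {
  set.seed(31)
  n <- 2^13
  depth <- rpois(n, 4) + c(rep(0, n / 2), rep(8, n / 2))
  depth[depth == 0] <- 1
  s <- compressLog(asTrack(depth))
  b <- trackBoundaries(s)
  expect_gt(length(b), 0)
  expect_lt(min(abs((GenomicRanges::start(b) - 1) - n / 2)), 200)
})

test_that("right boundaries are downward steps in the three_prime track", {
  set.seed(32)
  n <- 2^13
  depth <- rpois(n, 4) + c(rep(8, n / 2), rep(0, n / 2))
  depth[depth == 0] <- 1
  s <- compressLog(asTrack(depth, orientation = "three_prime"))
  b <- trackBoundaries(s)
  expect_gt(length(b), 0)
  expect_true(all(S4Vectors::mcols(b)$side == "right"))
  expect_lt(min(abs((GenomicRanges::start(b) - 1) - n / 2)), 200)
})
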