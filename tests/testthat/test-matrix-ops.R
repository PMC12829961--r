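# Binning, iterative-correction balancing, donut enrichment.

# high-precision Poisson upper tail by direct summation of P(X >= obs)
poisTailOracle <- function(obs, lambda) {
  if (obs <= 0) return(1)
  k <- obs:(obs + 1500)
  sum(exp(-lambda + k * log(lambda) - lgamma(k + 1)))
}

# a ContactMatrix built directly from a dense symmetric count matrix
makeMatrix <- function(M, resolution = 1000) {
  n <- nrow(M)
  up <- Matrix::triu(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                 "generalMatrix"))
  new("ContactMatrix", chrom = "chrT", resolution = resolution,
      counts = methods::as(up, "CsparseMatrix"),
      weights = rep(1, n), chromLength = n * resolution, balanced = TRUE)
}

test_that("binning uses half-open floor-division bins and conserves counts", {
  cp <- makePairs(pos1 = c(0, 5000, 100, 300), pos2 = c(9999, 5001, 5000, 700),
                  len = 2e4)
  cm <- binContacts(cp, "chrT", 5000)
  expect_equal(as.numeric(rawCounts(cm)[1, 2]), 2)  # (0,9999) and (100,5000)
  expect_equal(as.numeric(rawCounts(cm)[2, 2]), 1)  # pos 5000 -> bin 1
  expect_equal(as.numeric(rawCounts(cm)[1, 1]), 1)
  expect_equal(sum(rawCounts(cm)), length(cp))
})

test_that("balancing is a fixed point on equal marginals and converges", {
  n <- 8
  M <- matrix(1, n, n)
  cm <- makeMatrix(M)
  cm@balanced <- FALSE
  b <- balanceMatrix(cm, madCutoff = 10)
  w <- binWeights(b)
  expect_equal(w, rep(w[1], n), tolerance = 1e-6)

  set.seed(40)
  M2 <- matrix(rpois(n * n, 20), n, n)
  M2 <- M2 + t(M2)
  b2 <- balanceMatrix(makeMatrix(M2), madCutoff = 10)
  w2 <- binWeights(b2)
  bal <- (M2 / outer(w2, w2))
  marg <- rowSums(bal)
  expect_lt(stats::sd(marg) / mean(marg), 1e-3)

  M3 <- M2
  M3[3, ] <- 0
  M3[, 3] <- 0
  b3 <- balanceMatrix(makeMatrix(M3), madCutoff = 10)
  expect_true(is.na(binWeights(b3)[3]))
})

test_that("donut p-values match the Poisson tail oracle", {
  n <- 30
  cm <- makeMatrix(matrix(7, n, n))
  # uniform matrix: lambda equals the pixel value
  st <- donutPvalue(cm, 5, 20)
  expect_equal(st$lambda, 7, tolerance = 1e-12)
  expect_equal(st$p, poisTailOracle(7, 7), tolerance = 1e-12)

  M <- matrix(10, n, n)
  M[6, 21] <- M[21, 6] <- 30
  st2 <- donutPvalue(makeMatrix(M), 5, 20)
  expect_equal(st2$obs, 30)
  expect_equal(st2$p, poisTailOracle(30, 10), tolerance = 1e-10)
  expect_lt(st2$p, 1e-4)

  M0 <- matrix(5, n, n)
  M0[6, 21] <- M0[21, 6] <- 0
  expect_equal(donutPvalue(makeMatrix(M0), 5, 20)$p, 1)

  set.seed(41)
  for (k in 1:100) {
    obs <- sample(0:60, 1)
    lam <- runif(1, 0.2, 40)
    expect_equal(ppois(obs - 1, lam, lower.tail = FALSE),
                 poisTailOracle(obs, lam), tolerance = 1e-10)
  }
})

test_that("donut p is batch-stable and monotone in planted enrichment", {
  n <- 40
  set.seed(42)
  base <- matrix(rpois(n * n, 15), n, n)
  base <- base + t(base)
  ps <- vapply(c(1, 2, 4, 8), function(k) {
    M <- base
    M[8, 25] <- M[25, 8] <- round(15 * k)
    donutPvalue(makeMatrix(M), 7, 24)$p
  }, 1)
  expect_true(all(diff(ps) < 0))

  M <- base
  single <- donutPvalue(makeMatrix(M), 7, 24)
  batch <- donutPvalue(makeMatrix(M), c(7, 10, 12), c(24, 28, 30))
  expect_equal(batch$p[1], single$p)
})

test_that("anchor scan keeps the minimum donut p and drops dot-less candidates", {
  fx <- smokeFixture()
  f <- filterPairs(fx$sim$pairs)
  mats <- lapply(c(5e3, 1e4), function(r)
    balanceMatrix(binContacts(f, "chrS", r)))
  cands <- data.frame(chrom = "chrS",
                      start = c(2e5, 3.1e5), end = c(4.5e5, 5.2e5),
                      pairP = c(1e-6, 1e-6))
  sc <- scanAnchors(cands, mats)
  expect_equal(nrow(sc$candidates), 1L)   # only the planted corner survives
  expect_equal(sc$candidates$start, 2e5)
  aRes <- sc$anchors
  expect_true(all(c("resolution", "binI", "binJ", "p") %in% names(aRes)))
  # ANCp is the smallest significant p among overlapping calls
  overl <- aRes[abs(aRes$binI * aRes$resolution - 2e5) <= 2 * aRes$resolution &
                  abs(aRes$binJ * aRes$resolution - 4.5e5) <= 2 * aRes$resolution, ]
  expect_equal(sc$candidates$ANCp, max(min(overl$p), 1e-100))
})
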