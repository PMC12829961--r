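# Boundary-concordance metrics, polarization index, quantile correlation.

test_that("fuzzy matching counts are asymmetric under broad leeway", {
  expect_equal(unname(matchBoundaries(c(100), c(95, 105), 10)), c(1, 2))
  a <- c(100, 300, 500)
  expect_equal(unname(matchBoundaries(a, a, 0)), c(3, 3))
  expect_equal(unname(matchBoundaries(c(100), c(200), 10)), c(0, 0))
})

test_that("Jaccard index follows the fuzzy-union definition", {
  a <- c(100, 300, 500)
  expect_equal(jaccardIndex(a, a, 10), 1)
  expect_equal(jaccardIndex(c(100), c(500), 10), 0)
  # mean intersection 1.5, union 1 + 2 - 1.5 = 1.5
  expect_equal(jaccardIndex(c(100), c(95, 105), 10), 1)
  expect_error(jaccardIndex(numeric(0), numeric(0), 10), "empty")
})

test_that("overlap coefficient uses minima on both axes", {
  a <- c(100, 300, 500)
  expect_equal(overlapCoefficient(a, a, 10), 1)
  expect_equal(overlapCoefficient(c(100), c(95, 105), 10), 1)
  expect_equal(overlapCoefficient(c(100, 500), c(100), 0), 1)
  expect_error(overlapCoefficient(a, numeric(0), 10), "empty")
})

test_that("JI and oc are symmetric and ordered", {
  set.seed(60)
  for (k in 1:20) {
    a <- sort(sample(1e5, 30))
    b <- sort(sample(1e5, 20))
    lw <- sample(c(0, 100, 1000), 1)
    expect_equal(jaccardIndex(a, b, lw), jaccardIndex(b, a, lw))
    expect_equal(overlapCoefficient(a, b, lw), overlapCoefficient(b, a, lw))
    ji <- jaccardIndex(a, b, lw)
    oc <- overlapCoefficient(a, b, lw)
    expect_gte(oc, ji - 1e-12)
    expect_true(ji >= 0 && oc <= 1)
  }
})

test_that("TPR and FDR follow the matched-call definitions", {
  r <- c(100, 200, 300)
  expect_equal(unname(tprFdr(r, r, 10)), c(1, 0))
  expect_equal(unname(tprFdr(numeric(0), r, 10)), c(0, 0))
  expect_equal(unname(tprFdr(c(100, 250), r, 10)), c(1 / 3, 1 / 2))
  expect_error(tprFdr(c(100), numeric(0), 10), "empty reference")
})

test_that("convex hull volume and containment are exact on a cube", {
  pts <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set.seed(61)
  inner <- matrix(runif(60, 0.1, 0.9), ncol = 3)
  hull <- convexHull3d(rbind(pts, inner))
  expect_equal(hull$volume, 1, tolerance = 1e-9)
  expect_true(all(pointsInHull(hull, inner)))
  expect_false(any(pointsInHull(hull, matrix(c(2, 2, 2), 1))))
  expect_error(convexHull3d(cbind(runif(10), runif(10), 0)), "degenerate")
})

test_that("polarization index matches its closed forms", {
  set.seed(62)
  A <- matrix(runif(60), ncol = 3)
  B <- A + 10                        # disjoint hulls
  expect_equal(polarizationIndex(A, B)$PI, 1)
  expect_equal(polarizationIndex(A, A)$PI, 0, tolerance = 1e-9)

  # Va = Vb = 2, Vs = 1 -> PI = 0.5 (Monte-Carlo intersection)
  boxA <- as.matrix(expand.grid(0:1, 0:1, c(0, 2)))
  boxB <- as.matrix(expand.grid(0:1, 0:1, c(1, 3)))
  pi2 <- polarizationIndex(boxA, boxB, nSamples = 2e5)
  expect_equal(pi2$Va, 2, tolerance = 1e-9)
  expect_equal(pi2$Vs, 1, tolerance = 0.02)
  expect_equal(pi2$PI, 0.5, tolerance = 0.02)
})

test_that("polarization index is rigid-motion invariant", {
  set.seed(63)
  A <- matrix(rnorm(45), ncol = 3)
  B <- matrix(rnorm(45, 1), ncol = 3)
  p0 <- polarizationIndex(A, B)$PI
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -3, 2)
  p1 <- polarizationIndex(sweep(A %*% R, 2, -shift),
                          sweep(B %*% R, 2, -shift))$PI
  expect_equal(p0, p1, tolerance = 0.03)
})

test_that("quantile correlation recovers monotone links and matches cor", {
  n <- 200
  strengths <- sort(runif(n))
  freqs <- 1 / (strengths + 0.1)     # frequent TADs are strong (small TADp)
  expect_equal(strengthQuantileCorrelation(strengths, freqs, 25), 1)
  expect_equal(strengthQuantileCorrelation(strengths, rev(freqs), 25), -1)

  set.seed(64)
  fr <- runif(n)
  got <- strengthQuantileCorrelation(strengths, fr, 10)
  bin <- ceiling(rank(strengths, ties.method = "first") / (n / 10))
  oracle <- cor(tapply(strengths, bin, mean), 1 / tapply(fr, bin, mean),
                method = "spearman")
  expect_equal(got, oracle)
  expect_error(strengthQuantileCorrelation(rep(1, 50), runif(50), 10),
               "all strengths equal")
})
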