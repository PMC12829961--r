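# Comparison statistics between boundary sets and related evaluation
# metrics: fuzzy-match counts, modified Jaccard index, overlap
# coefficient, TPR/FDR, compartment polarization index, and the
# strength-frequency quantile correlation.

# accept GRanges of width-1 boundary calls or plain numeric bp positions
.asPositions <- function(x) {
  if (is(x, "GRanges")) return(sort(GenomicRanges::start(x) - 1))
  sort(as.numeric(x))
}

# number of elements of a with at least one element of b within leeway
.countMatched <- function(a, b, leeway) {
  if (!length(a) || !length(b)) return(0L)
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(b))
  near <- abs(b[lo] - a) <= leeway | abs(b[hi] - a) <= leeway
  sum(near)
}

#' Fuzzy boundary matching
#'
#' Counts, for each direction, the boundaries of one set having at least
#' one boundary of the other within \code{leeway} bp. With a broad leeway
#' one boundary can match several, so the two counts may differ.
#'
#' @param a,b boundary sets: width-1 GRanges or numeric bp positions.
#' @param leeway matching tolerance in bp (>= 0); the field's "one bin"
#'   convention maps to leeway = the comparator's bin size.
#' @return named numeric: \code{AB} (= |A intersect B|) and \code{BA}.
#' @export
matchBoundaries <- function(a, b, leeway) {
  stopifnot(leeway >= 0)
  a <- .asPositions(a)
  b <- .asPositions(b)
  c(AB = .countMatched(a, b, leeway), BA = .countMatched(b, a, leeway))
}

#' Modified Jaccard index between boundary sets
#'
#' JI = mean(|A^B|, |B^A|) / |A u B| with the fuzzy intersection counts of
#' \code{\link{matchBoundaries}} and the union defined as
#' |A| + |B| - mean(|A^B|, |B^A|), so that identical sets score exactly 1.
#'
#' @inheritParams matchBoundaries
#' @return a fraction in [0, 1].
#' @export
jaccardIndex <- function(a, b, leeway) {
  a <- .asPositions(a)
  b <- .asPositions(b)
  if (!length(a) && !length(b))
    stop("Jaccard index undefined for two empty boundary sets")
  m <- matchBoundaries(a, b, leeway)
  inter <- mean(m)
  union <- length(a) + length(b) - inter
  inter / union
}

#' Overlap coefficient between boundary sets
#'
#' oc = min(|A^B|, |B^A|) / min(|A|, |B|).
#'
#' @inheritParams matchBoundaries
#' @return a fraction in [0, 1].
#' @export
overlapCoefficient <- function(a, b, leeway) {
  a <- .asPositions(a)
  b <- .asPositions(b)
  if (!length(a) || !length(b))
    stop("overlap coefficient undefined for an empty boundary set")
  m <- matchBoundaries(a, b, leeway)
  min(m) / min(length(a), length(b))
}

#' True positive rate and false discovery rate of boundary calls
#'
#' TP: calls matching the reference within leeway; FN: reference
#' boundaries unmatched by any call; FP: calls unmatched by the
#' reference. TPR = TP / (TP + FN); FDR = FP / (FP + TP), defined as 0
#' when no positives were called.
#'
#' @param calls,reference boundary sets (GRanges or numeric positions).
#' @param leeway matching tolerance in bp.
#' @return named numeric: \code{TPR}, \code{FDR}.
#' @export
tprFdr <- function(calls, reference, leeway) {
  calls <- .asPositions(calls)
  reference <- .asPositions(reference)
  if (!length(reference))
    stop("TPR undefined: empty reference set")
  TP <- .countMatched(calls, reference, leeway)
  FP <- length(calls) - TP
  FN <- length(reference) - .countMatched(reference, calls, leeway)
  if (TP + FN == 0) stop("TPR undefined: TP + FN is zero")
  TPR <- TP / (TP + FN)
  FDR <- if (TP + FP == 0) 0 else FP / (FP + TP)
  c(TPR = TPR, FDR = FDR)
}

#' Compartment polarization index
#'
#' For two compartments given as 3D point clouds (e.g. TAD centroids from
#' imaging), PI = sqrt((1 - Vs/Va) (1 - Vs/Vb)) where Va, Vb are the
#' convex-hull volumes and Vs their shared (intersection) volume. PI is 1
#' when the hulls are disjoint (full spatial polarization) and 0 when
#' identical.
#'
#' @param pointsA,pointsB numeric matrices (n x 3) of 3D coordinates.
#' @param nSamples Monte-Carlo sample size for the intersection volume.
#' @param seed seed for the Monte-Carlo sampling (deterministic result).
#' @return list with \code{PI, Va, Vb, Vs}.
#' @export
polarizationIndex <- function(pointsA, pointsB, nSamples = 1e5, seed = 1L) {
  hullA <- convexHull3d(pointsA)
  hullB <- convexHull3d(pointsB)
  Vs <- hullIntersectionVolume(hullA, hullB, nSamples = nSamples, seed = seed)
  Vs <- min(Vs, hullA$volume, hullB$volume)
  pi_ <- sqrt((1 - Vs / hullA$volume) * (1 - Vs / hullB$volume))
  list(PI = pi_, Va = hullA$volume, Vb = hullB$volume, Vs = Vs)
}

#' Strength-frequency quantile correlation
#'
#' Bins per-TAD strengths (TADp) into equal-count quantiles, and
#' Spearman-correlates the mean strength per quantile with the inverse
#' mean structure frequency per quantile (frequent TADs have small TADp,
#' so a faithful strength measure gives a strong positive rank
#' correlation).
#'
#' @param strengths per-TAD TADp values.
#' @param frequencies per-TAD frequencies (fraction of cells / samples in
#'   which the TAD is observed), matched to \code{strengths}.
#' @param nQuantiles number of quantiles (commonly 10, 25, 50 or 100).
#' @return Spearman's rank correlation of the quantile summaries.
#' @export
strengthQuantileCorrelation <- function(strengths, frequencies,
                                        nQuantiles = 25) {
  stopifnot(length(strengths) == length(frequencies),
            nQuantiles <= length(strengths))
  if (length(unique(strengths)) == 1L)
    stop("correlation undefined: all strengths equal")
  rk <- rank(strengths, ties.method = "first")
  bin <- ceiling(rk / (length(strengths) / nQuantiles))
  bin <- pmin(bin, nQuantiles)
  meanS <- tapply(strengths, bin, mean)
  meanF <- tapply(frequencies, bin, mean)
  cor(as.numeric(meanS), 1 / as.numeric(meanF), method = "spearman")
}
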