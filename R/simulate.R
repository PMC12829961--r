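# Synthetic Hi-C contact generator with planted, fully known TAD/loop
# structure: power-law distance-decay background, block-enriched
# intra-TAD contacts, and corner-dot anchor contacts, at configurable
# read depth and per-TAD cell fraction.

#' Construct a simulation specification
#'
#' @param chromLength chromosome length in bp.
#' @param tads data.frame with columns \code{start, end} and optionally
#'   \code{intra_weight} (default 0.5), \code{anchor_weight} (default
#'   0.1) and \code{fraction} (default 1): relative sampling weights of
#'   block-enriched intra-TAD contacts and corner-dot anchor contacts,
#'   and the fraction of cells carrying the TAD.
#' @param nPairs number of contact pairs.
#' @param backgroundWeight relative weight of distance-decay background
#'   contacts (default 1).
#' @param decayExponent background P(d) ~ d^-exponent (default 1, the
#'   canonical Hi-C contact decay).
#' @param readLength read length in bp (default 50).
#' @param anchorWidth half-width of the corner-dot zone in bp (default
#'   2000, about one bin at 5 kb resolution).
#' @param chrom chromosome name (default "chrS").
#' @param seed RNG seed (default 1).
#' @return a \code{\link{SimSpec}}.
#' @export
simSpec <- function(chromLength, tads = NULL, nPairs,
                    backgroundWeight = 1, decayExponent = 1,
                    readLength = 50, anchorWidth = 2000,
                    chrom = "chrS", seed = 1L) {
  if (is.null(tads))
    tads <- data.frame(start = numeric(0), end = numeric(0))
  tads <- as.data.frame(tads)
  if (nrow(tads)) {
    if (is.null(tads$intra_weight)) tads$intra_weight <- 0.5
    if (is.null(tads$anchor_weight)) tads$anchor_weight <- 0.1
    if (is.null(tads$fraction)) tads$fraction <- 1
  } else {
    tads <- data.frame(start = numeric(0), end = numeric(0),
                       intra_weight = numeric(0), anchor_weight = numeric(0),
                       fraction = numeric(0))
  }
  new("SimSpec", chrom = chrom, chromLength = chromLength, tads = tads,
      backgroundWeight = backgroundWeight, decayExponent = decayExponent,
      nPairs = nPairs, readLength = readLength, anchorWidth = anchorWidth,
      seed = as.integer(seed))
}

# inverse-CDF sampler for P(d) ~ d^-e on [dmin, dmax]
.sampleDecayDistance <- function(n, e, dmin, dmax) {
  u <- runif(n)
  if (abs(e - 1) < 1e-12) {
    dmin * (dmax / dmin)^u
  } else {
    (dmin^(1 - e) + u * (dmax^(1 - e) - dmin^(1 - e)))^(1 / (1 - e))
  }
}

#' Simulate Hi-C contact pairs with planted structure
#'
#' Each pair is drawn from one of three components, with probability
#' proportional to its weight: (i) background, with genomic distance d
#' following a truncated power law P(d) ~ d^-exponent on [500 bp, 5 Mb]
#' and a uniform location; (ii) intra-TAD, both ends uniform within a
#' planted TAD chosen proportional to intra_weight * fraction (ends at
#' least 500 bp apart); (iii) anchor, both ends within +/- anchorWidth of
#' the TAD's (start, end) corner, chosen proportional to
#' anchor_weight * fraction. The upstream end becomes the 5' read, the
#' downstream end the 3' read. Deterministic for a given seed.
#'
#' @param spec a \code{\link{SimSpec}}.
#' @return list with \code{pairs} (a \code{\link{ContactPairs}}),
#'   \code{truth} (GRanges of the planted boundaries, with \code{side})
#'   and \code{tads} (the planted TAD table).
#' @export
simulateContacts <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  methods::validObject(spec)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec@seed)

  L <- spec@chromLength
  rl <- spec@readLength
  aw <- spec@anchorWidth
  t <- spec@tads
  nT <- nrow(t)
  wts <- c(spec@backgroundWeight,
           if (nT) t$intra_weight * t$fraction,
           if (nT) t$anchor_weight * t$fraction)
  comp <- sample.int(length(wts), spec@nPairs, replace = TRUE, prob = wts)
  pos5 <- numeric(spec@nPairs)
  pos3 <- numeric(spec@nPairs)

  bg <- which(comp == 1L)
  if (length(bg)) {
    dmax <- min(5e6, L - rl - 1)
    d <- round(.sampleDecayDistance(length(bg), spec@decayExponent, 500, dmax))
    p5 <- floor(runif(length(bg)) * (L - rl - d))
    pos5[bg] <- p5
    pos3[bg] <- p5 + d
  }
  for (k in seq_len(nT)) {
    idx <- which(comp == 1L + k)
    if (length(idx)) {
      lo <- t$start[k]
      hi <- t$end[k] - rl
      a <- floor(runif(length(idx), lo, hi))
      b <- floor(runif(length(idx), lo, hi))
      redo <- which(abs(a - b) < 500)
      while (length(redo)) {
        b[redo] <- floor(runif(length(redo), lo, hi))
        redo <- redo[abs(a[redo] - b[redo]) < 500]
      }
      pos5[idx] <- pmin(a, b)
      pos3[idx] <- pmax(a, b)
    }
    idx <- which(comp == 1L + nT + k)
    if (length(idx)) {
      p5 <- floor(runif(length(idx), t$start[k] - aw, t$start[k] + aw))
      p3 <- floor(runif(length(idx), t$end[k] - aw, t$end[k] + aw))
      pos5[idx] <- pmax(0, p5)
      pos3[idx] <- pmin(L - rl - 1, p3)
    }
  }
  tab <- data.frame(
    chrom1 = spec@chrom, pos1 = pos5, strand1 = "+", mapq1 = 60,
    chrom2 = spec@chrom, pos2 = pos3, strand2 = "-", mapq2 = 60,
    stringsAsFactors = FALSE)
  pairs <- new("ContactPairs", pairs = tab,
               chromSizes = setNames(L, spec@chrom), readLength = rl,
               provenance = list(source = "simulateContacts",
                                 seed = spec@seed))
  truth <- if (nT) {
    GenomicRanges::GRanges(
      seqnames = spec@chrom,
      ranges = IRanges::IRanges(start = c(t$start, t$end) + 1, width = 1),
      side = rep(c("left", "right"), each = nT))
  } else {
    GenomicRanges::GRanges()
  }
  list(pairs = pairs, truth = sort(truth), tads = t)
}

#' Mix contacts from two simulation specifications
#'
#' Pairs are drawn from spec A's generator with probability \code{ratio}
#' and from spec B's otherwise, keeping \code{nPairs} total; emulates a
#' heterogeneous cell population mixing two genome states.
#'
#' @param specA,specB \code{\link{SimSpec}} objects sharing the same
#'   chromosome and length.
#' @param ratio probability of drawing from A, in [0, 1].
#' @param nPairs total number of pairs.
#' @param seed RNG seed.
#' @return a \code{\link{ContactPairs}} object.
#' @export
mixtureContacts <- function(specA, specB, ratio, nPairs, seed = 1L) {
  if (ratio < 0 || ratio > 1) stop("ratio must lie in [0, 1]")
  stopifnot(specA@chromLength == specB@chromLength,
            specA@chrom == specB@chrom)
  seed <- as.integer(seed)
  withN <- function(spec, n, s) {
    spec@nPairs <- n
    spec@seed <- s
    spec
  }
  if (ratio == 1) return(simulateContacts(withN(specA, nPairs, seed))$pairs)
  if (ratio == 0) return(simulateContacts(withN(specB, nPairs, seed))$pairs)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fromA <- runif(nPairs) < ratio
  nA <- sum(fromA)
  pa <- simulateContacts(withN(specA, max(nA, 1L), seed + 1L))$pairs
  pb <- simulateContacts(withN(specB, max(nPairs - nA, 1L), seed + 2L))$pairs
  tab <- rbind(if (nA) pairsTable(pa)[seq_len(nA), ],
               if (nPairs - nA) pairsTable(pb)[seq_len(nPairs - nA), ])
  ord <- integer(nPairs)
  ord[fromA] <- seq_len(nA)
  ord[!fromA] <- nA + seq_len(nPairs - nA)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  new("ContactPairs", pairs = tab, chromSizes = chromSizes(pa),
      readLength = readLength(pa),
      provenance = list(source = "mixtureContacts", ratio = ratio,
                        seed = seed))
}

#' Write contact pairs in 4DN pairs format
#'
#' @param pairs a \code{\link{ContactPairs}} object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  sz <- chromSizes(pairs)
  for (i in seq_along(sz))
    writeLines(sprintf("#chromsize: %s %g", names(sz)[i], sz[[i]]), con)
  writeLines("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2", con)
  p <- pairsTable(pairs)
  if (nrow(p)) {
    writeLines(sprintf("r%d\t%s\t%.0f\t%s\t%.0f\t%s\t%s",
                       seq_len(nrow(p)), p$chrom1, p$pos1, p$chrom2, p$pos2,
                       p$strand1, p$strand2), con)
  }
  invisible(path)
}
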