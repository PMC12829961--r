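# Significance of detail coefficients under the wavelet-variance null and
# merging of significant runs into left/right boundary calls.

# smallest probability a boundary component is allowed to carry; keeps
# products of components (TADp) positive and -log10 strengths finite
.P_FLOOR <- 1e-100

#' Conservative wavelet-variance null
#'
#' Estimates the scale-1 coefficient variance and derives the null variance
#' used at every scale. Under independent noise the detail-coefficient
#' variance halves with each increasing scale; because genomic coverage is
#' not independent at fine scales, testing at scale j conservatively
#' assumes the (larger) variance implied for the previous scale j-1:
#' sigma2_null(1) = sigma2_1 and sigma2_null(j) = sigma2_1 / 2^(j-2) for
#' j >= 2.
#'
#' Two equivalent-under-independence forms of the previous-scale rule are
#' available. \code{"cascade"} extrapolates the whole ladder from scale 1:
#' sigma2_null(j) = sigma2_1 / 2^(j-2). \code{"empirical"} uses the
#' measured sample variance of the scale j-1 coefficients, floored at the
#' current scale's own sample variance (boundary responses are sparse, so
#' the scale's variance is noise-dominated under the null); the two forms
#' coincide in expectation for independent noise, but the empirical form
#' stays conservative when the coverage is serially correlated (it always
#' is, over the read length), which the cascade extrapolation does not.
#' The pipeline uses \code{"empirical"}.
#'
#' @param decomp a \code{\link{WaveletDecomposition}}.
#' @param robust use a MAD-based scale-1 variance estimate instead of the
#'   sample variance (default FALSE; cascade method only).
#' @param method \code{"cascade"} or \code{"empirical"} (see above).
#' @return list with \code{sigma2_1} and \code{sigma2_null} (length J).
#' @export
scaleNull <- function(decomp, robust = FALSE,
                      method = c("cascade", "empirical")) {
  method <- match.arg(method)
  stopifnot(is(decomp, "WaveletDecomposition"))
  w1 <- decomp@details[[1L]]
  if (length(w1) < 2L) stop("scale 1 must have at least 2 coefficients")
  s1 <- if (robust) mad(w1)^2 else var(w1)
  if (!is.finite(s1) || s1 <= 0)
    stop("degenerate (zero-variance) scale-1 coefficients: no signal")
  j <- seq_len(decomp@J)
  s <- if (method == "cascade") {
    ifelse(j == 1L, s1, s1 / 2^(j - 2L))
  } else {
    vj <- vapply(j, function(k) var(decomp@details[[k]]), 1)
    c(s1, pmax(vj[-length(vj)], vj[-1L])[seq_len(decomp@J - 1L)])
  }
  list(sigma2_1 = s1, sigma2_null = s, method = method)
}

#' Per-coefficient one-sided p-values with Holm adjustment
#'
#' Detail coefficients are asymptotically normal with mean 0 under the
#' null; each aligned coefficient is standardized by the conservative null
#' standard deviation of its scale and converted to an upper-tail p-value
#' oriented so that upward coverage steps (the boundary signature) fall in
#' the rejection region. Holm step-down adjustment is applied over the
#' whole family: all scales and positions of this signal.
#'
#' The tested family may exclude the finest scales (\code{scales}
#' argument): scales whose filter support is below the read length see
#' the discreteness of sparse per-base coverage (single-read pileup
#' edges), not contact-frequency changes, and serve only to estimate the
#' noise; the Holm family covers the tested scales and positions.
#'
#' @param decomp a \code{\link{WaveletDecomposition}}.
#' @param null output of \code{\link{scaleNull}}.
#' @param align advance coefficients by the filter's step-response peak
#'   before testing (default TRUE); unshifted coefficients lag the
#'   driving signal feature by about the filter width.
#' @param scales integer vector of scale indices to test (default: all).
#' @return list with \code{raw} and \code{adjusted} (lists of per-scale
#'   numeric vectors of the signal's length, indexed as in
#'   \code{scales}) and \code{scales}.
#' @export
coefficientPvalues <- function(decomp, null, align = TRUE, scales = NULL) {
  stopifnot(is(decomp, "WaveletDecomposition"))
  filt <- coifletFilter()
  sgn <- .stepSign(filt)
  if (is.null(scales)) scales <- seq_len(decomp@J)
  n <- length(decomp@signal@values)
  raw <- vector("list", length(scales))
  for (k in seq_along(scales)) {
    j <- scales[k]
    w <- decomp@details[[j]]
    if (align) w <- .alignCoefficients(w, j, filt)
    z <- sgn * w / sqrt(null$sigma2_null[j])
    raw[[k]] <- pnorm(z, lower.tail = FALSE)
  }
  adj <- p.adjust(unlist(raw, use.names = FALSE), method = "holm")
  adjusted <- lapply(seq_along(scales), function(k)
    adj[((k - 1) * n + 1):(k * n)])
  list(raw = raw, adjusted = adjusted, scales = scales)
}

#' Merge significant positions into boundary calls
#'
#' Positions with Holm-adjusted p <= alpha are retained per scale; maximal
#' runs of consecutive compressed indices collapse to a single call at the
#' rounded (half-up) mean genomic position of the run, carrying the run's
#' minimum adjusted p-value and its scale. Runs lying within one
#' equivalent-filter width of either signal end are discarded: those
#' coefficients mix both chromosome ends through the circular convolution
#' and respond to the spurious wrap-around discontinuity rather than to a
#' genomic feature. Calls from all scales are pooled and sorted; the same
#' boundary detected at several scales yields several nearby calls, later
#' reconciled by \code{\link{diamondRefine}}.
#'
#' @param pvals output of \code{\link{coefficientPvalues}}.
#' @param signal the underlying \code{\link{CompressedSignal}}.
#' @param side \code{"left"} (five_prime) or \code{"right"} (three_prime).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return a \code{GRanges} of width-1 boundary positions (0-based start
#'   reported via standard 1-based GRanges convention) with metadata
#'   columns \code{side}, \code{scale}, \code{p_adj} and \code{support}
#'   (the scale's filter width mapped to bp, used as a clustering radius).
#' @export
callBoundaries <- function(pvals, signal, side = c("left", "right"),
                           alpha = 0.05) {
  side <- match.arg(side)
  stopifnot(is(signal, "CompressedSignal"))
  imap <- signal@indexMap
  n <- length(imap)
  spacing <- if (n > 1L) median(abs(diff(imap))) else 1
  out <- list()
  testedScales <- if (!is.null(pvals$scales)) pvals$scales
                  else seq_along(pvals$adjusted)
  for (k in seq_along(pvals$adjusted)) {
    j <- testedScales[k]
    Lj <- (2^j - 1) * 5 + 1
    sig <- which(pvals$adjusted[[k]] <= alpha)
    # circularity-affected zone at both signal ends
    sig <- sig[sig > Lj & sig <= n - Lj]
    if (!length(sig)) next
    runStart <- c(TRUE, diff(sig) != 1L)
    runId <- cumsum(runStart)
    pos <- vapply(split(imap[sig], runId),
                  function(g) floor(mean(g) + 0.5), 1)
    pmin_ <- vapply(split(pvals$adjusted[[k]][sig], runId), min, 1)
    out[[length(out) + 1L]] <- data.frame(
      pos = as.numeric(pos), scale = j,
      p_adj = pmax(pmin_, .P_FLOOR),
      support = Lj * spacing
    )
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      side = character(0), scale = integer(0), p_adj = numeric(0),
      support = numeric(0))
    return(gr)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$pos, tab$scale), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = signal@chrom,
    ranges = IRanges::IRanges(start = tab$pos + 1, width = 1),
    side = side, scale = as.integer(tab$scale), p_adj = tab$p_adj,
    support = tab$support)
  gr
}

#' Default maximum decomposition scale
#'
#' The smallest J whose equivalent-filter support, in compressed
#' coordinates, covers the maximum TAD size mapped through the median
#' compressed spacing, capped at floor(log2 N) - 2.
#'
#' @param signal a \code{\link{CompressedSignal}}.
#' @param maxSize maximum structure size in bp (default 5e6).
#' @return integer J >= 1.
#' @export
chooseMaxScale <- function(signal, maxSize = 5e6) {
  n <- length(signal@values)
  if (n < 8L) stop("signal too short for decomposition")
  spacing <- max(1, median(abs(diff(signal@indexMap))))
  target <- maxSize / spacing
  feasible <- floor(log2((n - 1) / 5 + 1))  # largest j with filter width <= N
  cap <- max(1L, min(as.integer(floor(log2(n)) - 2L), as.integer(feasible)))
  j <- 1L
  while ((2^j - 1) * 5 + 1 < target && j < cap) j <- j + 1L
  j
}

#' Boundary calls for one strand-oriented coverage track
#'
#' End-to-end wavelet boundary detection for one compressed signal:
#' decomposition, conservative null, one-sided Holm-adjusted p-values, and
#' run merging. Left boundaries are upward coverage steps in the
#' five_prime track; right boundaries are downward steps in the
#' three_prime track, detected by running the same upward-step machinery
#' on the reversed signal.
#'
#' @param signal a \code{\link{CompressedSignal}}.
#' @param alpha significance level (default 0.05).
#' @param J maximum scale; default \code{\link{chooseMaxScale}}.
#' @param maxSize maximum structure size in bp (feeds the default J).
#' @param robust robust scale-1 variance estimate (default FALSE).
#' @param nullMethod variance-null form (see \code{\link{scaleNull}});
#'   the empirical previous-scale variance by default, which stays
#'   conservative on serially correlated coverage.
#' @param minSupport smallest tested filter support in bp (default 50,
#'   one read length): finer scales see the discreteness of per-base
#'   coverage rather than contact-frequency changes and only inform the
#'   variance null.
#' @return GRanges of boundary calls (possibly empty); see
#'   \code{\link{callBoundaries}}.
#' @export
trackBoundaries <- function(signal, alpha = 0.05, J = NULL, maxSize = 5e6,
                            robust = FALSE, nullMethod = "empirical",
                            minSupport = 50) {
  stopifnot(is(signal, "CompressedSignal"))
  if (length(signal@values) < 64L) {
    return(callBoundaries(list(adjusted = list()), signal,
                          side = if (signal@orientation == "five_prime")
                            "left" else "right", alpha = alpha))
  }
  side <- if (signal@orientation == "five_prime") "left" else "right"
  if (signal@orientation == "three_prime") {
    signal <- new("CompressedSignal", values = rev(signal@values),
                  indexMap = rev(signal@indexMap), chrom = signal@chrom,
                  orientation = signal@orientation)
  }
  if (is.null(J)) J <- chooseMaxScale(signal, maxSize)
  dec <- modwtDetail(signal, J = J)
  nullv <- scaleNull(dec, robust = robust, method = nullMethod)
  spacing <- max(1, median(abs(diff(signal@indexMap))))
  support <- ((2^seq_len(J) - 1) * 5 + 1) * spacing
  scales <- which(support >= minSupport)
  if (!length(scales)) scales <- J
  pv <- coefficientPvalues(dec, nullv, scales = scales)
  callBoundaries(pv, signal, side = side, alpha = alpha)
}

#' Export boundary calls as BED
#'
#' Six-column BED: chrom, pos, pos+1, side, -log10(p_adj), strand ('+' for
#' left, '-' for right boundaries).
#'
#' @param boundaries GRanges from \code{\link{trackBoundaries}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
exportBoundariesBED <- function(boundaries, path) {
  m <- S4Vectors::mcols(boundaries)
  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(boundaries)),
    start = GenomicRanges::start(boundaries) - 1,
    end = GenomicRanges::start(boundaries),
    name = m$side,
    score = round(-log10(m$p_adj), 4),
    strand = ifelse(m$side == "left", "+", "-"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
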