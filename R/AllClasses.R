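#' @import methods
#' @importClassesFrom S4Vectors Rle
#' @importClassesFrom Matrix Matrix
#' @importFrom stats var ppois pnorm p.adjust runif rnorm cor median mad
#'   wilcox.test rpois quantile setNames sd
#' @importFrom utils head tail read.delim write.table
NULL

#' ContactPairs: a set of parsed Hi-C contact pairs
#'
#' Holds the raw evidence stream of a Hi-C experiment: one row per read
#' pair, with the mapped position, strand and mapping quality of each end.
#' Both intra- and interchromosomal records are retained at parse time;
#' \code{\link{filterPairs}} reduces the set to valid intrachromosomal
#' contacts inside the configured insert-length window.
#'
#' Coordinates are 0-based. Each end is a point position extended to a
#' read interval of \code{readLength(x)} bases (half-open) when coverage is
#' computed.
#'
#' @slot pairs data.frame with columns \code{chrom1, pos1, strand1, mapq1,
#'   chrom2, pos2, strand2, mapq2}.
#' @slot chromSizes named numeric vector, chromosome name -> length (bp).
#' @slot readLength single numeric, pseudo-read length in bp used to extend
#'   point positions into read intervals.
#' @slot provenance list recording the source path and the filter
#'   parameters applied so far.
#' @export
setClass("ContactPairs",
  representation(
    pairs = "data.frame",
    chromSizes = "numeric",
    readLength = "numeric",
    provenance = "list"
  ),
  prototype(
    pairs = data.frame(
      chrom1 = character(), pos1 = numeric(), strand1 = character(),
      mapq1 = numeric(), chrom2 = character(), pos2 = numeric(),
      strand2 = character(), mapq2 = numeric(),
      stringsAsFactors = FALSE
    ),
    chromSizes = setNames(numeric(0), character(0)),
    readLength = 50,
    provenance = list()
  )
)

setValidity("ContactPairs", function(object) {
  p <- object@pairs
  need <- c("chrom1", "pos1", "strand1", "mapq1",
            "chrom2", "pos2", "strand2", "mapq2")
  if (!all(need %in% names(p)))
    return(paste("pairs table must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) > 0L) {
    sz <- object@chromSizes
    bad <- !(p$chrom1 %in% names(sz)) | !(p$chrom2 %in% names(sz))
    if (any(bad))
      return(sprintf("chromosome absent from chromSizes: %s",
                     paste(unique(c(p$chrom1, p$chrom2)[
                       !(c(p$chrom1, p$chrom2) %in% names(sz))]),
                       collapse = ", ")))
    if (any(p$pos1 < 0) || any(p$pos2 < 0))
      return("negative positions")
    if (any(p$pos1 >= sz[p$chrom1]) || any(p$pos2 >= sz[p$chrom2]))
      return("position beyond chromosome length")
  }
  if (length(object@readLength) != 1L || object@readLength <= 0)
    return("readLength must be a single positive number")
  TRUE
})

#' CoverageTrack: per-base read coverage for one strand-oriented group
#'
#' @slot chrom chromosome name.
#' @slot orientation \code{"five_prime"} (upstream read ends) or
#'   \code{"three_prime"} (downstream read ends).
#' @slot depth integer-Rle of per-base depth over \code{[0, chromLength)}.
#' @slot chromLength chromosome length in bp.
#' @export
setClass("CoverageTrack",
  representation(
    chrom = "character",
    orientation = "character",
    depth = "Rle",
    chromLength = "numeric"
  )
)

setValidity("CoverageTrack", function(object) {
  if (!object@orientation %in% c("five_prime", "three_prime"))
    return("orientation must be 'five_prime' or 'three_prime'")
  if (length(object@depth) != object@chromLength)
    return("depth length must equal chromLength")
  if (any(S4Vectors::runValue(object@depth) < 0))
    return("depth must be non-negative")
  TRUE
})

#' CompressedSignal: log coverage with zero positions removed
#'
#' The wavelet input: log-transformed depth at the positions with nonzero
#' coverage, together with an index map from compressed index back to the
#' 0-based genomic position.
#'
#' @slot values numeric, log depth at nonzero positions, genomic order.
#' @slot indexMap numeric, strictly monotone 0-based genomic positions
#'   (increasing for five_prime tracks; reversed tracks used internally
#'   during right-boundary detection carry a decreasing map).
#' @slot chrom chromosome name.
#' @slot orientation as in \code{\link{CoverageTrack}}.
#' @export
setClass("CompressedSignal",
  representation(
    values = "numeric",
    indexMap = "numeric",
    chrom = "character",
    orientation = "character"
  )
)

setValidity("CompressedSignal", function(object) {
  if (length(object@values) != length(object@indexMap))
    return("values and indexMap must have equal length")
  if (length(object@indexMap) > 1L) {
    d <- diff(object@indexMap)
    if (!(all(d > 0) || all(d < 0)))
      return("indexMap must be strictly monotone")
  }
  TRUE
})

#' WaveletDecomposition: MODWT detail coefficients of a compressed signal
#'
#' @slot signal the decomposed \code{\link{CompressedSignal}}.
#' @slot details list of numeric vectors; element j holds the scale-j
#'   detail coefficients (length N, non-decimated).
#' @slot smooth numeric, the level-J scaling coefficients (for exact
#'   reconstruction).
#' @slot J number of scales.
#' @slot filterName analyzing filter identifier (\code{"c6"}).
#' @export
setClass("WaveletDecomposition",
  representation(
    signal = "CompressedSignal",
    details = "list",
    smooth = "numeric",
    J = "integer",
    filterName = "character"
  )
)

setValidity("WaveletDecomposition", function(object) {
  n <- length(object@signal@values)
  if (length(object@details) != object@J)
    return("details must hold one vector per scale")
  if (any(vapply(object@details, length, 1L) != n))
    return("each detail vector must have the signal's length (MODWT)")
  if (length(object@smooth) != n)
    return("smooth must have the signal's length")
  TRUE
})

#' ContactMatrix: a binned intrachromosomal contact matrix
#'
#' Sparse, upper-triangular storage of binned contact counts at one
#' resolution, with per-bin multiplicative balancing weights after
#' \code{\link{balanceMatrix}} (balanced value = count / (w_i * w_j); NA
#' weight marks a bin flagged invalid for low coverage).
#'
#' @slot chrom chromosome name.
#' @slot resolution bin size in bp.
#' @slot counts \code{dgCMatrix}, upper triangle (i <= j), raw counts.
#' @slot weights numeric per-bin balancing factors (NA = invalid bin).
#' @slot chromLength chromosome length in bp.
#' @slot balanced logical, whether \code{balanceMatrix} has run.
#' @export
setClass("ContactMatrix",
  representation(
    chrom = "character",
    resolution = "numeric",
    counts = "Matrix",
    weights = "numeric",
    chromLength = "numeric",
    balanced = "logical"
  )
)

setValidity("ContactMatrix", function(object) {
  n <- nrow(object@counts)
  if (ncol(object@counts) != n) return("counts must be square")
  if (length(object@weights) != n)
    return("weights must have one entry per bin")
  if (object@resolution <= 0) return("resolution must be positive")
  if (any(object@counts@x < 0)) return("counts must be non-negative")
  TRUE
})

#' SimSpec: specification of a synthetic Hi-C contact sample
#'
#' Describes the generative conditions for \code{\link{simulateContacts}}:
#' a power-law distance-decay background, block-enriched intra-TAD
#' contacts for each planted TAD, and corner-dot anchor contacts at each
#' TAD's (start, end) apex. \code{fraction} emulates structural
#' heterogeneity: the share of cells in which the TAD is present.
#'
#' @slot chrom chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot tads data.frame with columns \code{start, end, intra_weight,
#'   anchor_weight, fraction}.
#' @slot backgroundWeight relative sampling weight of background contacts.
#' @slot decayExponent background P(distance d) ~ d^-exponent.
#' @slot nPairs number of contact pairs to draw.
#' @slot readLength read length in bp.
#' @slot anchorWidth half-width (bp) of the corner-dot anchor zone.
#' @slot seed RNG seed (integer); same seed, same pairs.
#' @export
setClass("SimSpec",
  representation(
    chrom = "character",
    chromLength = "numeric",
    tads = "data.frame",
    backgroundWeight = "numeric",
    decayExponent = "numeric",
    nPairs = "numeric",
    readLength = "numeric",
    anchorWidth = "numeric",
    seed = "integer"
  )
)

setValidity("SimSpec", function(object) {
  t <- object@tads
  if (nrow(t) > 0L) {
    need <- c("start", "end", "intra_weight", "anchor_weight", "fraction")
    if (!all(need %in% names(t)))
      return(paste("tads must have columns:", paste(need, collapse = ", ")))
    span <- t$end - t$start
    if (any(span < 4e4) || any(span > 5e6))
      return("planted TAD spans must lie in [40 kb, 5 Mb]")
    if (any(t$start < 0) || any(t$end > object@chromLength))
      return("planted TAD outside chromosome")
    if (any(t$fraction <= 0) || any(t$fraction > 1))
      return("fractions must lie in (0, 1]")
  }
  if (object@nPairs <= 0) return("nPairs must be positive")
  if (object@decayExponent <= 0) return("decayExponent must be positive")
  if (object@chromLength <= 0) return("chromLength must be positive")
  TRUE
})

# ---- accessors ---------------------------------------------------------

#' @describeIn ContactPairs number of pairs
#' @param x,object a ContactPairs object
#' @export
setMethod("length", "ContactPairs", function(x) nrow(x@pairs))

#' Accessors for waveTAD classes
#'
#' @param x an object of the documented class
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pairsTable", function(x) standardGeneric("pairsTable"))
#' @rdname accessors
#' @export
setMethod("pairsTable", "ContactPairs", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname accessors
#' @export
setMethod("chromSizes", "ContactPairs", function(x) x@chromSizes)

#' @rdname accessors
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))
#' @rdname accessors
#' @export
setMethod("readLength", "ContactPairs", function(x) x@readLength)

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setMethod("signalValues", "CompressedSignal", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("indexMap", function(x) standardGeneric("indexMap"))
#' @rdname accessors
#' @export
setMethod("indexMap", "CompressedSignal", function(x) x@indexMap)

#' @rdname accessors
#' @export
setGeneric("detailCoefficients", function(x, j) standardGeneric("detailCoefficients"))
#' @rdname accessors
#' @param j scale index
#' @export
setMethod("detailCoefficients", "WaveletDecomposition",
          function(x, j) x@details[[j]])

#' @rdname accessors
#' @export
setGeneric("binWeights", function(x) standardGeneric("binWeights"))
#' @rdname accessors
#' @export
setMethod("binWeights", "ContactMatrix", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("matrixResolution", function(x) standardGeneric("matrixResolution"))
#' @rdname accessors
#' @export
setMethod("matrixResolution", "ContactMatrix", function(x) x@resolution)

#' @rdname accessors
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))
#' @rdname accessors
#' @export
setMethod("rawCounts", "ContactMatrix", function(x) x@counts)

# ---- show methods ------------------------------------------------------

setMethod("show", "ContactPairs", function(object) {
  cat(sprintf("ContactPairs: %d pairs on %d chromosome(s)\n",
              nrow(object@pairs), length(object@chromSizes)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "CompressedSignal", function(object) {
  cat(sprintf("CompressedSignal: %s [%s], %d nonzero positions\n",
              object@chrom, object@orientation, length(object@values)))
})

setMethod("show", "WaveletDecomposition", function(object) {
  cat(sprintf("WaveletDecomposition: %d scales (%s), N = %d\n",
              object@J, object@filterName, length(object@signal@values)))
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %s @ %g bp, %d bins, %s\n",
              object@chrom, object@resolution, nrow(object@counts),
              if (object@balanced) "balanced" else "raw"))
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf("SimSpec: %s (%g bp), %d planted TAD(s), %g pairs, seed %d\n",
              object@chrom, object@chromLength, nrow(object@tads),
              object@nPairs, object@seed))
})
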