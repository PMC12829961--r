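# Contact input: parsing, filtering, strand-orientation and per-base
# coverage of valid Hi-C contact pairs.

#' Read chromosome sizes
#'
#' Two-column text: chromosome name, TAB, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chrom.sizes must have two columns")
  setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' Parse Hi-C contact pairs
#'
#' Reads 4DN pairs-format text (columns readID, chrom1, pos1, chrom2, pos2,
#' strand1, strand2; '#'-prefixed header lines, with chromosome lengths in
#' '#chromsize:' lines) or a simple contact-table TSV (chrom1, pos1,
#' strand1, pos2, strand2[, mapq], one chromosome per record pair column
#' layout: chrom, pos1, strand1, pos2, strand2[, mapq]). All parseable
#' records are returned, including interchromosomal ones; filtering is a
#' separate step (\code{\link{filterPairs}}).
#'
#' @param path file path.
#' @param format \code{"pairs"}, \code{"table"} or \code{"auto"} (pairs if
#'   the first line starts with \code{"## pairs"} or \code{"#"}).
#' @param chromSizes named numeric vector; may be omitted for pairs files
#'   with \code{#chromsize:} headers.
#' @param readLength pseudo-read length (bp) used to extend each point end
#'   into a read interval when computing coverage (input-dialect decision;
#'   positions-only inputs carry no alignment length).
#' @return a \code{\link{ContactPairs}} object.
#' @examples
#' tf <- tempfile()
#' writeLines(c("## pairs format v1.0", "#chromsize: chrA 100000",
#'   "r1\tchrA\t100\tchrA\t5000\t+\t-"), tf)
#' parseContacts(tf)
#' @export
parseContacts <- function(path, format = c("auto", "pairs", "table"),
                          chromSizes = NULL, readLength = 50) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (length(lines) && startsWith(lines[1L], "#")) "pairs" else "table"
  }
  isHeader <- startsWith(lines, "#")
  if (format == "pairs") {
    cs <- grep("^#chromsize:", lines, value = TRUE)
    if (length(cs)) {
      fields <- strsplit(sub("^#chromsize:\\s*", "", cs), "\\s+")
      hdrSizes <- setNames(vapply(fields, function(f) as.numeric(f[2L]), 1),
                           vapply(fields, function(f) f[1L], ""))
      if (is.null(chromSizes)) chromSizes <- hdrSizes
    }
  }
  if (is.null(chromSizes))
    stop("chromSizes must be supplied or embedded in the pairs header")

  body <- which(!isHeader & nzchar(lines))
  mk <- function(chrom1, pos1, strand1, mapq1, chrom2, pos2, strand2, mapq2) {
    data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1, mapq1 = mapq1,
               chrom2 = chrom2, pos2 = pos2, strand2 = strand2, mapq2 = mapq2,
               stringsAsFactors = FALSE)
  }
  if (!length(body)) {
    obj <- new("ContactPairs", chromSizes = chromSizes,
               readLength = readLength,
               provenance = list(source = path, format = format))
    return(obj)
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "pairs") {
    bad <- which(nf < 7L)
    if (length(bad))
      stop(sprintf("malformed pairs line %d: expected >= 7 tab fields, got %d",
                   body[bad[1L]], nf[bad[1L]]))
    m <- do.call(rbind, lapply(fields, function(f) f[2:7]))
    tab <- mk(m[, 1L], suppressWarnings(as.numeric(m[, 2L])), m[, 5L], NA_real_,
              m[, 3L], suppressWarnings(as.numeric(m[, 4L])), m[, 6L], NA_real_)
  } else {
    bad <- which(nf < 5L)
    if (length(bad))
      stop(sprintf("malformed table line %d: expected >= 5 tab fields, got %d",
                   body[bad[1L]], nf[bad[1L]]))
    m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
    mapq <- suppressWarnings(as.numeric(m[, 6L]))
    tab <- mk(m[, 1L], suppressWarnings(as.numeric(m[, 2L])), m[, 3L], mapq,
              m[, 1L], suppressWarnings(as.numeric(m[, 4L])), m[, 5L], mapq)
  }
  badPos <- which(is.na(tab$pos1) | is.na(tab$pos2))
  if (length(badPos))
    stop(sprintf("malformed line %d: non-numeric position", body[badPos[1L]]))
  unknown <- setdiff(unique(c(tab$chrom1, tab$chrom2)), names(chromSizes))
  if (length(unknown))
    stop("unknown chromosome in input: ", paste(unknown, collapse = ", "))
  new("ContactPairs", pairs = tab, chromSizes = chromSizes,
      readLength = readLength,
      provenance = list(source = path, format = format))
}

#' Filter contact pairs
#'
#' Retains intrachromosomal pairs whose insert (span from the upstream read
#' start to the downstream read end) lies inside the inclusive
#' \code{[minInsert, maxInsert]} window and whose mapping qualities pass
#' \code{minMapq} (records without a mapq are treated as passing). Order is
#' preserved; filtering is idempotent.
#'
#' @param x a \code{\link{ContactPairs}} object.
#' @param minInsert minimum insert length in bp (default 500).
#' @param maxInsert maximum insert length in bp (default 5e6).
#' @param minMapq minimum mapping quality (default 30, operationalizing
#'   unique mapping; NA mapq passes).
#' @param dedup remove exact-coordinate duplicate pairs (default FALSE).
#' @return the filtered \code{ContactPairs}.
#' @export
filterPairs <- function(x, minInsert = 500, maxInsert = 5e6, minMapq = 30,
                        dedup = FALSE) {
  stopifnot(is(x, "ContactPairs"), minInsert > 0, maxInsert >= minInsert)
  p <- x@pairs
  rl <- x@readLength
  keep <- p$chrom1 == p$chrom2
  ins <- abs(p$pos2 - p$pos1) + rl
  keep <- keep & ins >= minInsert & ins <= maxInsert
  mq1 <- ifelse(is.na(p$mapq1), Inf, p$mapq1)
  mq2 <- ifelse(is.na(p$mapq2), Inf, p$mapq2)
  keep <- keep & mq1 >= minMapq & mq2 >= minMapq
  p <- p[keep, , drop = FALSE]
  if (dedup && nrow(p))
    p <- p[!duplicated(p[, c("chrom1", "pos1", "pos2", "strand1", "strand2")]), ,
           drop = FALSE]
  rownames(p) <- NULL
  prov <- x@provenance
  prov$filter <- list(minInsert = minInsert, maxInsert = maxInsert,
                      minMapq = minMapq, dedup = dedup)
  initialize(x, pairs = p, provenance = prov)
}

#' Strand-oriented per-base coverage
#'
#' Splits each filtered pair into its 5' (upstream, leftmost start) and 3'
#' (downstream) read, and accumulates per-base depth for the two groups
#' independently: the upstream read interval contributes +1 per base to the
#' five_prime track, the downstream one to the three_prime track.
#'
#' @param x a filtered \code{\link{ContactPairs}} object.
#' @param chrom chromosome to process.
#' @return list with \code{five_prime} and \code{three_prime}
#'   \code{\link{CoverageTrack}} objects.
#' @export
orientAndCoverage <- function(x, chrom) {
  stopifnot(is(x, "ContactPairs"))
  if (!chrom %in% names(x@chromSizes))
    stop("chromosome absent from chromSizes: ", chrom)
  len <- x@chromSizes[[chrom]]
  p <- x@pairs
  p <- p[p$chrom1 == chrom & p$chrom2 == chrom, , drop = FALSE]
  rl <- x@readLength
  up <- pmin(p$pos1, p$pos2)
  down <- pmax(p$pos1, p$pos2)
  covOf <- function(starts) {
    s <- pmax(0, pmin(starts, len - rl))
    # 0-based [s, s+rl) -> 1-based IRanges
    IRanges::coverage(IRanges::IRanges(start = s + 1, width = rl), width = len)
  }
  list(
    five_prime = new("CoverageTrack", chrom = chrom,
                     orientation = "five_prime", depth = covOf(up),
                     chromLength = len),
    three_prime = new("CoverageTrack", chrom = chrom,
                      orientation = "three_prime", depth = covOf(down),
                      chromLength = len)
  )
}

#' Compress and log-transform a coverage track
#'
#' Removes zero-coverage positions and natural-log transforms the
#' remaining depths; the index map records the 0-based genomic position of
#' every compressed index. An all-zero track yields an empty signal.
#'
#' @param track a \code{\link{CoverageTrack}}.
#' @return a \code{\link{CompressedSignal}}.
#' @export
compressLog <- function(track) {
  stopifnot(is(track, "CoverageTrack"))
  depth <- track@depth
  rv <- S4Vectors::runValue(depth)
  rlens <- S4Vectors::runLength(depth)
  ends <- cumsum(rlens)
  starts <- ends - rlens + 1L
  keep <- which(rv > 0)
  if (!length(keep)) {
    return(new("CompressedSignal", values = numeric(0), indexMap = numeric(0),
               chrom = track@chrom, orientation = track@orientation))
  }
  pos1 <- unlist(lapply(keep, function(k) starts[k]:ends[k]), use.names = FALSE)
  vals <- rep(log(rv[keep]), rlens[keep])
  new("CompressedSignal", values = vals, indexMap = as.numeric(pos1 - 1L),
      chrom = track@chrom, orientation = track@orientation)
}

#' Export a coverage track as bedGraph
#'
#' @param track a \code{\link{CoverageTrack}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
exportCoverageBedGraph <- function(track, path) {
  depth <- track@depth
  rv <- S4Vectors::runValue(depth)
  rlens <- S4Vectors::runLength(depth)
  ends <- cumsum(rlens)
  starts <- ends - rlens
  keep <- rv > 0
  tab <- data.frame(chrom = track@chrom, start = starts[keep],
                    end = ends[keep], value = rv[keep])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
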