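# Assembly of boundary calls into scored TAD/loop calls: exhaustive
# pairing inside the size window, diamond-statistic refinement of
# multi-scale boundary clusters, strength scoring, and TSV round-trip.

#' Pair left and right boundaries into candidate TADs/loops
#'
#' Forms every (left, right) combination with left < right whose span lies
#' in the inclusive \code{[minSize, maxSize]} window; the pair probability
#' is the product of the two boundary probabilities.
#'
#' @param leftSet,rightSet boundary GRanges from
#'   \code{\link{trackBoundaries}} (same chromosome, sorted).
#' @param minSize,maxSize span window in bp (defaults 40 kb and 5 Mb).
#' @param cap maximum number of candidates retained per chromosome; above
#'   it only the smallest pair probabilities are kept (default 1e6).
#' @return data.frame with one candidate per row: \code{chrom, start, end,
#'   Lp, Rp, pairP, leftScale, rightScale, leftSupport, rightSupport},
#'   sorted by (start, end).
#' @export
pairBoundaries <- function(leftSet, rightSet, minSize = 4e4, maxSize = 5e6,
                           cap = 1e6) {
  emptyCand <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), Lp = numeric(0), Rp = numeric(0),
                          pairP = numeric(0), leftScale = integer(0),
                          rightScale = integer(0), leftSupport = numeric(0),
                          rightSupport = numeric(0))
  if (!length(leftSet) || !length(rightSet)) return(emptyCand)
  lpos <- GenomicRanges::start(leftSet) - 1
  rpos <- GenomicRanges::start(rightSet) - 1
  lm <- S4Vectors::mcols(leftSet)
  rm_ <- S4Vectors::mcols(rightSet)
  ord <- order(rpos)
  rpos <- rpos[ord]
  rm_ <- rm_[ord, , drop = FALSE]
  rows <- vector("list", length(lpos))
  for (i in seq_along(lpos)) {
    lo <- lpos[i] + minSize
    hi <- lpos[i] + maxSize
    k1 <- findInterval(lo - 0.5, rpos) + 1L
    k2 <- findInterval(hi + 0.5, rpos)
    if (k2 < k1) next
    idx <- k1:k2
    rows[[i]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(leftSet))[i],
      start = lpos[i], end = rpos[idx],
      Lp = lm$p_adj[i], Rp = rm_$p_adj[idx],
      pairP = lm$p_adj[i] * rm_$p_adj[idx],
      leftScale = lm$scale[i], rightScale = rm_$scale[idx],
      leftSupport = lm$support[i], rightSupport = rm_$support[idx])
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(emptyCand)
  if (nrow(out) > cap) {
    message(sprintf("candidate cap: keeping %d of %d pairs by pair probability",
                    as.integer(cap), nrow(out)))
    out <- out[order(out$pairP)[seq_len(cap)], , drop = FALSE]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TopDom-style diamond p-value for a boundary at 0-based bin i: mean
# contact in the w x w diamond straddling i, rank-sum-tested (one-sided,
# less) against the within-region values flanking it.
.diamondP <- function(M, i0, w) {
  n <- nrow(M)
  i <- i0 + 1L                       # boundary between bin i and i+1 (1-based)
  if (i - w + 1L < 1L || i + w > n) return(NA_real_)
  rows <- (i - w + 1L):i
  cols <- (i + 1L):(i + w)
  cross <- as.vector(M[rows, cols, drop = FALSE])
  upL <- M[rows, rows, drop = FALSE]
  upR <- M[cols, cols, drop = FALSE]
  within <- c(upL[upper.tri(upL)], upR[upper.tri(upR)])
  cross <- cross[is.finite(cross)]
  within <- within[is.finite(within)]
  if (length(cross) < 3L || length(within) < 3L) return(NA_real_)
  suppressWarnings(
    wilcox.test(cross, within, alternative = "less", exact = FALSE)$p.value)
}

#' Refine multi-scale boundary clusters with the diamond statistic
#'
#' Wavelet leakage across scales can call the same broad boundary several
#' times at slightly shifted locations. Boundary calls of the same side
#' lying within a proximity radius (the larger of twice the finest matrix
#' resolution and the calls' wavelet support width) are clustered; each
#' cluster is replaced by the single member whose diamond statistic,
#' evaluated at resolutions keyed to the TAD span (largest resolution <=
#' span/10 and its next-finer neighbor), attains the minimum p-value (ties:
#' leftmost member). Isolated boundaries pass through unchanged; clusters
#' with no evaluable resolution keep their original calls.
#'
#' @param candidates anchored candidate data.frame (from
#'   \code{\link{scanAnchors}}).
#' @param matrices list of balanced \code{\link{ContactMatrix}} objects.
#' @param w diamond window in bins (default 5).
#' @return the refined candidate data.frame, duplicates collapsed (minimum
#'   pairP * ANCp kept) and columns \code{refineResLeft, refineResRight}
#'   recording the chosen resolution (NA where unrefined).
#' @export
diamondRefine <- function(candidates, matrices, w = 5) {
  if (!nrow(candidates)) {
    candidates$refineResLeft <- numeric(0)
    candidates$refineResRight <- numeric(0)
    return(candidates)
  }
  resAll <- sort(vapply(matrices, function(m) m@resolution, 1))
  finest <- resAll[1L]
  denseCache <- new.env(parent = emptyenv())
  getDense <- function(res) {
    key <- as.character(res)
    if (is.null(denseCache[[key]])) {
      cm <- matrices[[which(vapply(matrices, function(m) m@resolution, 1) == res)[1L]]]
      denseCache[[key]] <- list(M = .balancedDense(cm), cm = cm)
    }
    denseCache[[key]]
  }

  refineSide <- function(posCol, pCol, scaleCol, supportCol, resCol) {
    tab <- unique(candidates[, c(posCol, pCol, scaleCol, supportCol)])
    names(tab) <- c("pos", "p", "scale", "support")
    tab <- tab[order(tab$pos), , drop = FALSE]
    radius <- pmax(2 * finest, tab$support)
    newCluster <- c(TRUE, diff(tab$pos) >
                      pmax(head(radius, -1), tail(radius, -1)))
    cl <- cumsum(newCluster)
    mapPos <- tab$pos
    mapP <- tab$p
    mapScale <- tab$scale
    mapRes <- rep(NA_real_, nrow(tab))
    for (g in unique(cl)) {
      idx <- which(cl == g)
      if (length(idx) < 2L) next
      members <- tab$pos[idx]
      touching <- candidates[[posCol]] %in% members
      span <- median(candidates$end[touching] - candidates$start[touching])
      elig <- resAll[resAll <= span / 10]
      resSet <- if (length(elig)) {
        r1 <- max(elig)
        finer <- resAll[resAll < r1]
        c(if (length(finer)) max(finer), r1)
      } else resAll[1L]
      best <- NULL
      for (res in resSet) {
        dc <- getDense(res)
        for (m in seq_along(members)) {
          p <- .diamondP(dc$M, floor(members[m] / res), w)
          if (is.na(p)) next
          if (is.null(best) || p < best$p ||
              (p == best$p && members[m] < best$pos)) {
            best <- list(p = p, pos = members[m], member = idx[m], res = res)
          }
        }
      }
      if (is.null(best)) {
        message(sprintf("diamond refinement: cluster at %g not evaluable, keeping wavelet calls",
                        members[1L]))
        next
      }
      mapPos[idx] <- tab$pos[best$member]
      mapP[idx] <- tab$p[best$member]
      mapScale[idx] <- tab$scale[best$member]
      mapRes[idx] <- best$res
    }
    match_ <- match(candidates[[posCol]], tab$pos)
    candidates[[posCol]] <<- mapPos[match_]
    candidates[[pCol]] <<- mapP[match_]
    candidates[[scaleCol]] <<- mapScale[match_]
    candidates[[resCol]] <<- mapRes[match_]
    invisible(NULL)
  }

  candidates$refineResLeft <- NA_real_
  candidates$refineResRight <- NA_real_
  refineSide("start", "Lp", "leftScale", "leftSupport", "refineResLeft")
  refineSide("end", "Rp", "rightScale", "rightSupport", "refineResRight")
  candidates <- candidates[candidates$end - candidates$start > 0, , drop = FALSE]
  # collapse duplicates produced by cluster merging
  score <- candidates$pairP * candidates$ANCp
  ord <- order(candidates$start, candidates$end, score)
  candidates <- candidates[ord, , drop = FALSE]
  dup <- duplicated(candidates[, c("start", "end")])
  candidates <- candidates[!dup, , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

#' Score candidate TADs/loops
#'
#' The strength of a call is the product of its three component
#' probabilities, TADp = Lp * Rp * ANCp, reported alongside
#' -log10(TADp); smaller TADp (larger strength) marks a more frequent /
#' more stable structure. Overlapping and nested calls are all retained:
#' the output is hierarchical.
#'
#' @param candidates anchored (and optionally refined) candidate
#'   data.frame.
#' @return a sorted GRanges with metadata columns \code{Lp, Rp, ANCp,
#'   TADp, negLog10TADp, anchorRes} (plus refinement provenance when
#'   present).
#' @export
scoreTADs <- function(candidates) {
  if (!nrow(candidates)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      Lp = numeric(0), Rp = numeric(0), ANCp = numeric(0),
      TADp = numeric(0), negLog10TADp = numeric(0), anchorRes = numeric(0))
    return(gr)
  }
  Lp <- pmax(candidates$Lp, .P_FLOOR)
  Rp <- pmax(candidates$Rp, .P_FLOOR)
  ANCp <- pmax(candidates$ANCp, .P_FLOOR)
  gr <- GenomicRanges::GRanges(
    seqnames = candidates$chrom,
    ranges = IRanges::IRanges(start = candidates$start + 1,
                              end = candidates$end),
    Lp = Lp, Rp = Rp, ANCp = ANCp,
    TADp = Lp * Rp * ANCp,
    negLog10TADp = -(log10(Lp) + log10(Rp) + log10(ANCp)),
    anchorRes = candidates$anchorRes)
  if (!is.null(candidates$refineResLeft)) {
    S4Vectors::mcols(gr)$refineResLeft <- candidates$refineResLeft
    S4Vectors::mcols(gr)$refineResRight <- candidates$refineResRight
  }
  sort(gr)
}

#' Write / read scored TAD calls
#'
#' Tab-separated with header \code{chrom start end Lp Rp ANCp TADp
#' neg_log10_TADp}; coordinates 0-based half-open. Values round-trip at 12
#' significant digits.
#'
#' @param tads GRanges from \code{\link{scoreTADs}}.
#' @param path file path.
#' @return \code{writeCalls}: invisibly, the path. \code{readCalls}: a
#'   GRanges of calls.
#' @export
writeCalls <- function(tads, path) {
  m <- S4Vectors::mcols(tads)
  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tads)),
    start = GenomicRanges::start(tads) - 1,
    end = GenomicRanges::end(tads),
    Lp = sprintf("%.12g", m$Lp), Rp = sprintf("%.12g", m$Rp),
    ANCp = sprintf("%.12g", m$ANCp), TADp = sprintf("%.12g", m$TADp),
    neg_log10_TADp = sprintf("%.12g", m$negLog10TADp))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("chrom", "start", "end", "Lp", "Rp", "ANCp", "TADp",
            "neg_log10_TADp")
  if (!all(need %in% names(tab)))
    stop("malformed calls file: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (!nrow(tab)) {
    return(scoreTADs(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), Lp = numeric(0),
                                Rp = numeric(0), ANCp = numeric(0),
                                anchorRes = numeric(0))))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed calls file: non-numeric %s at line %d",
                   col, bad[1L] + 1L))
    v
  }
  GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = num("start") + 1, end = num("end")),
    Lp = num("Lp"), Rp = num("Rp"), ANCp = num("ANCp"), TADp = num("TADp"),
    negLog10TADp = num("neg_log10_TADp"))
}
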