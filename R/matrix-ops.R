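# Binned contact matrices: construction, iterative-correction balancing,
# and the donut (annulus) enrichment test at candidate apex pixels.

#' Bin contact pairs into a sparse matrix
#'
#' Each intrachromosomal pair adds one count to the half-open bin pair
#' (floor(pos5 / res), floor(pos3 / res)), where pos5 is the upstream read
#' start and pos3 the downstream read start; the matrix is stored as its
#' upper triangle.
#'
#' @param x a filtered \code{\link{ContactPairs}} object.
#' @param chrom chromosome.
#' @param resolution bin size in bp.
#' @return a \code{\link{ContactMatrix}}.
#' @export
binContacts <- function(x, chrom, resolution) {
  stopifnot(is(x, "ContactPairs"), resolution > 0)
  if (!chrom %in% names(x@chromSizes))
    stop("chromosome absent from chromSizes: ", chrom)
  len <- x@chromSizes[[chrom]]
  nbins <- as.integer(ceiling(len / resolution))
  p <- x@pairs
  p <- p[p$chrom1 == chrom & p$chrom2 == chrom, , drop = FALSE]
  if (nrow(p)) {
    i <- floor(pmin(p$pos1, p$pos2) / resolution) + 1
    j <- floor(pmax(p$pos1, p$pos2) / resolution) + 1
    counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                   dims = c(nbins, nbins))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(nbins, nbins))
  }
  new("ContactMatrix", chrom = chrom, resolution = resolution,
      counts = methods::as(counts, "CsparseMatrix"),
      weights = rep(1, nbins), chromLength = len, balanced = FALSE)
}

# full symmetric matrix from upper-triangular storage
.symCounts <- function(cm) {
  s <- cm@counts
  full <- s + Matrix::t(s)
  d <- Matrix::diag(s)
  if (any(d != 0)) full <- full - Matrix::Diagonal(nrow(s), d)
  full
}

#' Iterative-correction (ICE) balancing
#'
#' Computes multiplicative per-bin weights so that the marginals of the
#' balanced matrix (count / (w_i * w_j)) are equal over valid bins. Bins
#' with zero coverage, or with a raw marginal below a MAD-based
#' low-coverage cutoff (median - madCutoff * MAD of nonzero marginals),
#' are flagged invalid (weight NA) and excluded.
#'
#' @param cm a \code{\link{ContactMatrix}}.
#' @param tol convergence tolerance: coefficient of variation of
#'   valid-bin marginals (default 1e-5).
#' @param maxIter maximum iterations (default 200); non-convergence
#'   produces a warning and returns the best iterate.
#' @param madCutoff multiplier for the MAD low-coverage filter (default 3).
#' @return the balanced \code{ContactMatrix} (weights filled in).
#' @export
balanceMatrix <- function(cm, tol = 1e-5, maxIter = 200, madCutoff = 3) {
  stopifnot(is(cm, "ContactMatrix"))
  full <- .symCounts(cm)
  n <- nrow(full)
  marg <- as.numeric(Matrix::rowSums(full))
  nz <- marg[marg > 0]
  valid <- marg > 0
  if (length(nz) >= 4L) {
    cutoff <- median(nz) - madCutoff * mad(nz)
    valid <- valid & marg >= cutoff
  }
  b <- rep(1, n)
  if (!any(valid)) {
    b[] <- NA_real_
    return(initialize(cm, weights = b, balanced = TRUE))
  }
  ib <- ifelse(valid, 1, 0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    m <- as.numeric(full %*% ib) * ib
    mv <- m[valid]
    mbar <- mean(mv)
    cv <- stats::sd(mv) / mbar
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    s <- m / mbar
    b[valid] <- b[valid] * s[valid]
    ib <- ifelse(valid, 1 / b, 0)
  }
  if (!converged && maxIter > 1L)
    warning(sprintf("balancing did not reach tol = %g in %d iterations",
                    tol, maxIter))
  b[!valid] <- NA_real_
  initialize(cm, weights = b, balanced = TRUE)
}

# dense symmetric balanced matrix; rows/cols of invalid bins are NA
.balancedDense <- function(cm, maxBins = 4096L) {
  n <- nrow(cm@counts)
  if (n > maxBins)
    stop(sprintf("dense balanced matrix requested for %d bins (cap %d)",
                 n, maxBins))
  M <- as.matrix(.symCounts(cm))
  w <- cm@weights
  M <- M / outer(w, w)
  M
}

#' Donut enrichment p-value at focal pixels
#'
#' HiCCUPS-style local background test: the expected count at a focal
#' pixel is the mean of the balanced values over the surrounding donut
#' annulus (window half-width \code{w}, excluding the (2 pw + 1)^2 peak
#' box and the focal row/column arms), rescaled to raw-count space through
#' the focal bins' balancing weights; the p-value is the upper-tail
#' Poisson probability P(X >= observed | lambda).
#'
#' @param cm a balanced \code{\link{ContactMatrix}}.
#' @param binI,binJ 0-based focal bin indices (vectors of equal length,
#'   binI < binJ).
#' @param pw peak half-width in bins (default 2).
#' @param w window half-width in bins (default 5); must exceed \code{pw}.
#' @return data.frame with columns \code{binI, binJ, obs, lambda, ratio,
#'   p}; \code{p} is NA where the annulus holds no valid pixel.
#' @export
donutPvalue <- function(cm, binI, binJ, pw = 2, w = 5) {
  stopifnot(is(cm, "ContactMatrix"), w > pw, pw >= 1,
            length(binI) == length(binJ))
  if (!cm@balanced) stop("matrix must be balanced first")
  if (!length(binI))
    return(data.frame(binI = integer(0), binJ = integer(0), obs = numeric(0),
                      lambda = numeric(0), ratio = numeric(0), p = numeric(0)))
  n <- nrow(cm@counts)
  if (any(binI < 0 | binJ >= n | binI >= binJ))
    stop("focal pixels must satisfy 0 <= binI < binJ < nbins")
  M <- .balancedDense(cm)
  wt <- cm@weights
  offsets <- expand.grid(di = -w:w, dj = -w:w)
  inPeak <- abs(offsets$di) <= pw & abs(offsets$dj) <= pw
  inArm <- offsets$di == 0 | offsets$dj == 0
  offsets <- offsets[!(inPeak | inArm), , drop = FALSE]
  i1 <- binI + 1L
  j1 <- binJ + 1L
  acc <- numeric(length(binI))
  cnt <- numeric(length(binI))
  for (k in seq_len(nrow(offsets))) {
    ri <- i1 + offsets$di[k]
    cj <- j1 + offsets$dj[k]
    ok <- ri >= 1L & ri <= n & cj >= 1L & cj <= n
    v <- rep(NA_real_, length(binI))
    v[ok] <- M[cbind(ri[ok], cj[ok])]
    use <- ok & !is.na(v)
    acc[use] <- acc[use] + v[use]
    cnt[use] <- cnt[use] + 1
  }
  meanBal <- ifelse(cnt > 0, acc / cnt, NA_real_)
  lambda <- meanBal * wt[i1] * wt[j1]
  obs <- as.numeric(cm@counts[cbind(i1, j1)])
  p <- rep(NA_real_, length(obs))
  okl <- !is.na(lambda) & lambda > 0
  p[okl] <- ppois(obs[okl] - 1, lambda[okl], lower.tail = FALSE)
  data.frame(binI = binI, binJ = binJ, obs = obs, lambda = lambda,
             ratio = obs / lambda, p = p)
}

#' Donut validation of candidate apexes / loop anchors
#'
#' For each candidate TAD the donut test is evaluated at the apex pixel
#' (bin of the left boundary, bin of the right boundary) and its 1-bin
#' neighborhood at every configured resolution where it is defined.
#' Significant calls require p <= donutAlpha, at least \code{minObs} raw
#' contacts, and an observed/expected ratio of at least \code{minRatio}.
#' A candidate's anchor probability ANCp is the minimum p over all
#' significant overlapping calls; candidates with none are dropped.
#'
#' Adjacent significant pixels at one resolution are one physical corner
#' dot and are merged into a dot component; a component whose genomic
#' footprint is re-detected at a finer resolution is suppressed in favor
#' of the finer (better localized) one, and each retained component keeps
#' the single candidate with the strongest combined probability, so one
#' apex validates one structure rather than every near-duplicate boundary
#' pairing that brushes the smeared dot at coarse resolution.
#'
#' @param candidates data.frame with at least \code{start} and \code{end}
#'   (bp positions of the paired boundaries).
#' @param matrices list of balanced \code{\link{ContactMatrix}} objects
#'   (one per resolution).
#' @param donutAlpha significance threshold on the donut p (default 0.1).
#' @param pw,w donut geometry (defaults 2 and 5 bins).
#' @param minObs minimum raw contacts at the pixel (default 10).
#' @param minRatio minimum observed/expected enrichment (default 1.5).
#' @param maxDistance maximum anchor span in bp (default 5e6).
#' @param leewayBins neighborhood half-width in bins (default 1).
#' @return list with \code{candidates} (the surviving rows plus an
#'   \code{ANCp} column and \code{anchorRes}, the resolution of the dot
#'   component that retained the candidate) and \code{anchors} (one row
#'   per significant donut call: resolution, bins, obs, lambda, p, and
#'   the dot component id).
#' @export
scanAnchors <- function(candidates, matrices, donutAlpha = 0.1, pw = 2,
                        w = 5, minObs = 10, minRatio = 1.5,
                        maxDistance = 5e6, leewayBins = 1) {
  stopifnot(is.data.frame(candidates))
  nc <- nrow(candidates)
  empty <- function() {
    out <- candidates[integer(0), , drop = FALSE]
    out$ANCp <- numeric(0)
    out$anchorRes <- numeric(0)
    list(candidates = out, anchors = data.frame())
  }
  if (nc == 0L) return(empty())

  # significant donut pixels per resolution
  sigByRes <- list()
  for (cm in matrices) {
    res <- cm@resolution
    n <- nrow(cm@counts)
    bi0 <- floor(candidates$start / res)
    bj0 <- floor(candidates$end / res)
    eligible <- which(bj0 - bi0 > w &
                        (candidates$end - candidates$start) <= maxDistance)
    if (!length(eligible)) next
    offs <- expand.grid(di = -leewayBins:leewayBins,
                        dj = -leewayBins:leewayBins)
    pix <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
      cbind(bi = bi0[eligible] + offs$di[k], bj = bj0[eligible] + offs$dj[k]))))
    # besides staying off the diagonal, keep the whole window clear of the
    # distance ceiling (bin distance n): near it the feasible-position
    # range collapses and the local annulus no longer estimates the
    # background (long-range pairs funnel into the anti-diagonal corner)
    pix <- pix[pix[, 1] >= 0 & pix[, 2] < n & pix[, 2] - pix[, 1] > w &
                 pix[, 2] - pix[, 1] <= n - (2 * w + 1), , drop = FALSE]
    if (!nrow(pix)) next
    st <- donutPvalue(cm, pix[, 1], pix[, 2], pw = pw, w = w)
    sig <- !is.na(st$p) & st$p <= donutAlpha & st$obs >= minObs &
      st$ratio >= minRatio
    if (!any(sig)) next
    sigByRes[[as.character(res)]] <- st[sig, , drop = FALSE]
  }
  if (!length(sigByRes)) return(empty())

  # merge adjacent significant pixels into dot components (8-connectivity)
  comps <- list()
  for (resKey in names(sigByRes)) {
    res <- as.numeric(resKey)
    tab <- sigByRes[[resKey]]
    m <- nrow(tab)
    comp <- seq_len(m)
    repeat {
      changed <- FALSE
      for (a in seq_len(m)) {
        near <- abs(tab$binI - tab$binI[a]) <= 1 &
          abs(tab$binJ - tab$binJ[a]) <= 1
        target <- min(comp[near])
        if (any(comp[near] != target)) {
          comp[near] <- target
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    tab$component <- comp
    sigByRes[[resKey]] <- tab
    for (g in unique(comp)) {
      sub <- tab[comp == g, , drop = FALSE]
      comps[[length(comps) + 1L]] <- list(
        resolution = res, pixels = sub,
        minP = min(sub$p),
        box = c(i1 = min(sub$binI) * res, i2 = (max(sub$binI) + 1) * res,
                j1 = min(sub$binJ) * res, j2 = (max(sub$binJ) + 1) * res))
    }
  }
  # suppress a component re-detected at a finer resolution
  resOf <- vapply(comps, function(cc) cc$resolution, 1)
  keepComp <- rep(TRUE, length(comps))
  for (a in seq_along(comps)) {
    finer <- which(resOf < resOf[a])
    for (b in finer) {
      ba <- comps[[a]]$box
      bb <- comps[[b]]$box
      if (bb["i1"] < ba["i2"] && bb["i2"] > ba["i1"] &&
          bb["j1"] < ba["j2"] && bb["j2"] > ba["j1"]) {
        keepComp[a] <- FALSE
        break
      }
    }
  }
  comps <- comps[keepComp]
  if (!length(comps)) return(empty())

  # assign each candidate to the finest-resolution component whose pixel
  # set its apex overlaps within the leeway; ANCp = min p over all
  # overlapping components (minimum across resolutions)
  compIdx <- rep(NA_integer_, nc)
  ANCp <- rep(NA_real_, nc)
  ord <- order(vapply(comps, function(cc) cc$resolution, 1))
  for (ci in ord) {
    cc <- comps[[ci]]
    res <- cc$resolution
    bi0 <- floor(candidates$start / res)
    bj0 <- floor(candidates$end / res)
    hit <- rep(FALSE, nc)
    for (k in seq_len(nrow(cc$pixels))) {
      hit <- hit | (abs(bi0 - cc$pixels$binI[k]) <= leewayBins &
                      abs(bj0 - cc$pixels$binJ[k]) <= leewayBins)
    }
    hit <- hit & (candidates$end - candidates$start) <= maxDistance
    if (!any(hit)) next
    ANCp[hit] <- pmin(ANCp[hit], cc$minP, na.rm = TRUE)
    compIdx[hit & is.na(compIdx)] <- ci
  }
  anchored <- which(!is.na(compIdx))
  if (!length(anchored)) return(empty())
  # one structure per dot component: keep the strongest candidate
  combined <- candidates$pairP[anchored] * pmax(ANCp[anchored], .P_FLOOR)
  best <- tapply(seq_along(anchored), compIdx[anchored], function(ii)
    anchored[ii[which.min(combined[ii])]])
  keep <- sort(unlist(best))
  out <- candidates[keep, , drop = FALSE]
  out$ANCp <- pmax(ANCp[keep], .P_FLOOR)
  out$anchorRes <- vapply(compIdx[keep], function(ci) comps[[ci]]$resolution, 1)
  rownames(out) <- NULL
  anchorsTab <- do.call(rbind, lapply(names(sigByRes), function(resKey)
    cbind(resolution = as.numeric(resKey), sigByRes[[resKey]])))
  list(candidates = out, anchors = anchorsTab)
}
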