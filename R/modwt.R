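# Maximum-overlap discrete wavelet transform (MODWT) with the coiflet c6
# analyzing filter: pyramid algorithm, equivalent per-scale filters,
# multiresolution details for reconstruction, and coefficient alignment.

# coiflet c6 orthonormal scaling coefficients (sum = sqrt(2), sum sq = 1)
.C6_SCALING <- c(-0.015655728135791993, -0.07273261951252645,
                  0.3848648468648578,    0.8525720202116004,
                  0.3378976624574818,   -0.07273261951252645)

#' The coiflet c6 MODWT filter
#'
#' Returns the 6-tap coiflet analyzing filter in MODWT normalization: the
#' wavelet filter is the quadrature mirror of the scaling filter,
#' h_l = (-1)^l g_(L-1-l), and both are rescaled by 1/sqrt(2) so that
#' sum(h) = 0 and sum(h^2) = 1/2.
#'
#' @return list with elements \code{name}, \code{h} (wavelet filter),
#'   \code{g} (scaling filter) and \code{L} (filter width, 6).
#' @export
coifletFilter <- function() {
  g <- .C6_SCALING
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1L) * rev(g)
  list(name = "c6", h = h / sqrt(2), g = g / sqrt(2), L = L)
}

# circular right-shift: lagged series x_{t-k}
.circShift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

#' Equivalent MODWT filter at scale j
#'
#' Builds the width-\code{Lj = (2^j - 1)(L - 1) + 1} filter whose direct
#' circular convolution with the input reproduces the scale-j pyramid
#' output: the base wavelet (or scaling) filter upsampled by 2^(j-1) and
#' convolved with the equivalent scaling filter of scale j-1.
#'
#' @param j scale index (>= 1).
#' @param filter filter list from \code{\link{coifletFilter}}.
#' @param type \code{"wavelet"} or \code{"scaling"}.
#' @return numeric filter of width (2^j - 1)(L - 1) + 1.
#' @export
equivalentFilter <- function(j, filter = coifletFilter(),
                             type = c("wavelet", "scaling")) {
  type <- match.arg(type)
  upsample <- function(f, by) {
    if (by == 1L) return(f)
    out <- numeric((length(f) - 1L) * by + 1L)
    out[seq(1L, length(out), by = by)] <- f
    out
  }
  convFull <- function(a, b) {
    n <- length(a) + length(b) - 1L
    out <- numeric(n)
    for (i in which(a != 0)) {  # upsampled filters are mostly zeros
      idx <- i:(i + length(b) - 1L)
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  gj <- filter$g
  if (j == 1L)
    return(if (type == "wavelet") filter$h else filter$g)
  gprev <- filter$g
  for (k in 2:j) {
    base <- if (k == j && type == "wavelet") filter$h else filter$g
    cur <- convFull(upsample(base, 2L^(k - 1L)), gprev)
    if (k == j && type == "wavelet") return(cur)
    gprev <- cur
  }
  gprev
}

#' MODWT detail decomposition
#'
#' Computes the non-decimated MODWT of a compressed coverage signal with
#' the pyramid algorithm, returning one detail-coefficient vector of the
#' signal's length per scale. Circular treatment of the ends:
#' W_(j,t) = sum_l htilde_(j,l) X_((t - l) mod N). A constant signal has
#' all-zero detail coefficients at every scale.
#'
#' @param signal a \code{\link{CompressedSignal}} (or plain numeric vector,
#'   wrapped internally).
#' @param J number of scales; the equivalent filter at scale J must fit the
#'   signal, i.e. (2^J - 1)(L - 1) + 1 <= N.
#' @param filter filter list from \code{\link{coifletFilter}}.
#' @return a \code{\link{WaveletDecomposition}}.
#' @examples
#' x <- new("CompressedSignal", values = rnorm(64),
#'          indexMap = as.numeric(0:63), chrom = "c", orientation = "five_prime")
#' modwtDetail(x, J = 3)
#' @export
modwtDetail <- function(signal, J, filter = coifletFilter()) {
  if (is.numeric(signal)) {
    signal <- new("CompressedSignal", values = as.numeric(signal),
                  indexMap = as.numeric(seq_along(signal) - 1L),
                  chrom = "signal", orientation = "five_prime")
  }
  stopifnot(is(signal, "CompressedSignal"))
  x <- signal@values
  n <- length(x)
  J <- as.integer(J)
  if (J < 1L) stop("J must be >= 1")
  L <- filter$L
  Lj <- (2^J - 1) * (L - 1) + 1
  if (Lj > n) {
    maxJ <- if (n >= L) floor(log2((n - 1) / (L - 1) + 1)) else 0L
    stop(sprintf("J = %d too large for N = %d (filter width %g > N); max feasible J is %d",
                 J, n, Lj, as.integer(maxJ)))
  }
  h <- filter$h
  g <- filter$g
  details <- vector("list", J)
  v <- x
  for (j in seq_len(J)) {
    s <- 2L^(j - 1L)
    w <- h[1L] * v
    vn <- g[1L] * v
    for (l in 2:L) {
      lag <- .circShift(v, s * (l - 1L))
      w <- w + h[l] * lag
      vn <- vn + g[l] * lag
    }
    details[[j]] <- w
    v <- vn
  }
  new("WaveletDecomposition", signal = signal, details = details,
      smooth = v, J = J, filterName = filter$name)
}

#' Multiresolution details and smooth (exact reconstruction)
#'
#' Cross-correlates each scale's coefficients with its equivalent filter to
#' form the multiresolution analysis: the per-scale details plus the final
#' smooth reconstruct the input exactly.
#'
#' @param decomp a \code{\link{WaveletDecomposition}}.
#' @return list with \code{details} (list of numeric vectors) and
#'   \code{smooth}.
#' @export
modwtMRA <- function(decomp) {
  stopifnot(is(decomp, "WaveletDecomposition"))
  n <- length(decomp@signal@values)
  filt <- coifletFilter()
  xcorr <- function(w, f) {
    out <- f[1L] * w
    for (l in seq_along(f)[-1L]) {
      # advance: D_t uses W_{(t + l) mod N}
      out <- out + f[l] * .circShift(w, -(l - 1L))
    }
    out
  }
  details <- lapply(seq_len(decomp@J), function(j)
    xcorr(decomp@details[[j]], equivalentFilter(j, filt, "wavelet")))
  smooth <- xcorr(decomp@smooth, equivalentFilter(decomp@J, filt, "scaling"))
  list(details = details, smooth = smooth)
}

#' Step-response alignment shift for scale j
#'
#' The scale-j coefficient W_(j,t) summarizes signal values before t over
#' the equivalent filter's support, so the response to a coverage step
#' peaks after the step itself. The boundary signature is a step, so
#' coefficients are advanced by the lag at which the filter's unit-step
#' response (the running sum of its taps) peaks, centering the response
#' on the genomic location of the coverage change at every scale.
#'
#' @param j scale index.
#' @param filter filter list.
#' @return integer advance (positions).
#' @export
alignmentShift <- function(j, filter = coifletFilter()) {
  key <- paste0("shift_", filter$name, "_", j)
  if (!is.null(.waveTADcache[[key]])) return(.waveTADcache[[key]])
  hj <- equivalentFilter(j, filter, "wavelet")
  s <- which.max(abs(cumsum(hj))) - 1L
  .waveTADcache[[key]] <- s
  s
}

# advance coefficients so they are centered on the driving signal feature
.alignCoefficients <- function(w, j, filter = coifletFilter()) {
  .circShift(w, -alignmentShift(j, filter))
}

# Orientation calibration: sign by which aligned detail coefficients must
# be multiplied so that an upward step (low -> high coverage) falls in the
# upper tail. Fixed once per filter on a canonical synthetic step.
.waveTADcache <- new.env(parent = emptyenv())

.stepSign <- function(filter = coifletFilter()) {
  key <- paste0("stepSign_", filter$name)
  if (!is.null(.waveTADcache[[key]])) return(.waveTADcache[[key]])
  n <- 256L
  x <- c(rep(0, n / 2), rep(1, n / 2))
  dec <- modwtDetail(x, J = 3L, filter = filter)
  best <- 0
  for (j in 1:3) {
    wj <- .alignCoefficients(dec@details[[j]], j, filter)
    # look only near the step, away from the circular wrap
    win <- (n / 2 - 20):(n / 2 + 20)
    cand <- wj[win][which.max(abs(wj[win]))]
    if (abs(cand) > abs(best)) best <- cand
  }
  s <- if (best >= 0) 1 else -1
  .waveTADcache[[key]] <- s
  s
}
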