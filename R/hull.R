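# Minimal 3D convex hull (incremental algorithm), hull volume, point
# containment, and Monte-Carlo intersection volume. Used by the
# compartment polarization index.

#' 3D convex hull
#'
#' Incremental construction: starting from an extreme tetrahedron, each
#' remaining point outside the current hull removes its visible faces and
#' is stitched to the horizon edges. Degenerate inputs (fewer than four
#' points, or all points coplanar) are an error.
#'
#' @param points numeric matrix, n x 3.
#' @param eps numerical tolerance relative to the cloud's scale.
#' @return list with \code{vertices} (the input points), \code{faces}
#'   (m x 3 vertex indices, outward-oriented), \code{normals},
#'   \code{offsets} (face plane: normal . x <= offset inside) and
#'   \code{volume}.
#' @export
convexHull3d <- function(points, eps = 1e-9) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  n <- nrow(points)
  if (n < 4L) stop("degenerate hull: need at least 4 points")
  scale <- max(apply(points, 2, function(c) diff(range(c))), 1)
  tol <- eps * scale

  # initial extreme tetrahedron
  i1 <- which.min(points[, 1])
  d1 <- rowSums(sweep(points, 2, points[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= tol) stop("degenerate hull: coincident points")
  ab <- points[i2, ] - points[i1, ]
  crossLen <- function(v, w) {
    cv <- c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3],
            v[1] * w[2] - v[2] * w[1])
    cv
  }
  dLine <- apply(points, 1, function(p)
    sqrt(sum(crossLen(p - points[i1, ], ab)^2)) / sqrt(sum(ab^2)))
  i3 <- which.max(dLine)
  if (dLine[i3] <= tol) stop("degenerate hull: collinear points")
  nrm <- crossLen(points[i2, ] - points[i1, ], points[i3, ] - points[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dPlane <- abs(as.vector((points - matrix(points[i1, ], n, 3, byrow = TRUE)) %*% nrm))
  i4 <- which.max(dPlane)
  if (dPlane[i4] <= tol) stop("degenerate hull: coplanar points")

  centroid <- colMeans(points[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  facePlane <- function(f) {
    a <- points[f[1], ]; b <- points[f[2], ]; cc <- points[f[3], ]
    nv <- crossLen(b - a, cc - a)
    ln <- sqrt(sum(nv^2))
    if (ln <= tol^2) return(NULL)
    nv <- nv / ln
    off <- sum(nv * a)
    if (sum(nv * centroid) > off) { nv <- -nv; off <- -off }
    list(normal = nv, offset = off)
  }
  planes <- lapply(seq_len(nrow(faces)), function(k) facePlane(faces[k, ]))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    pt <- points[p, ]
    visible <- vapply(planes, function(pl)
      sum(pl$normal * pt) > pl$offset + tol, TRUE)
    if (!any(visible)) next
    visF <- faces[visible, , drop = FALSE]
    edges <- rbind(visF[, c(1, 2)], visF[, c(2, 3)], visF[, c(1, 3)])
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ek %in% names(which(table(ek) == 1L)), , drop = FALSE]
    faces <- faces[!visible, , drop = FALSE]
    planes <- planes[!visible]
    for (e in seq_len(nrow(horizon))) {
      f <- c(horizon[e, ], p)
      pl <- facePlane(f)
      if (is.null(pl)) next
      faces <- rbind(faces, f)
      planes <- c(planes, list(pl))
    }
  }
  vol <- 0
  for (k in seq_len(nrow(faces))) {
    a <- points[faces[k, 1], ] - centroid
    b <- points[faces[k, 2], ] - centroid
    cc <- points[faces[k, 3], ] - centroid
    vol <- vol + abs(sum(a * crossLen(b, cc))) / 6
  }
  list(vertices = points, faces = faces,
       normals = t(vapply(planes, function(pl) pl$normal, numeric(3))),
       offsets = vapply(planes, function(pl) pl$offset, 1),
       volume = vol)
}

#' Test points for convex-hull membership
#'
#' @param hull output of \code{\link{convexHull3d}}.
#' @param points numeric matrix, m x 3.
#' @param eps tolerance.
#' @return logical vector of length m.
#' @export
pointsInHull <- function(hull, points, eps = 1e-9) {
  points <- as.matrix(points)
  s <- points %*% t(hull$normals)
  apply(sweep(s, 2, hull$offsets) <= eps, 1, all)
}

#' Monte-Carlo intersection volume of two convex hulls
#'
#' Uniform rejection sampling over the intersection of the two bounding
#' boxes; deterministic for a given seed. Returns 0 immediately when the
#' bounding boxes are disjoint.
#'
#' @param hullA,hullB outputs of \code{\link{convexHull3d}}.
#' @param nSamples Monte-Carlo sample size (default 1e5).
#' @param seed RNG seed for the sampling (default 1); the caller's RNG
#'   state is left untouched.
#' @return estimated shared volume.
#' @export
hullIntersectionVolume <- function(hullA, hullB, nSamples = 1e5, seed = 1L) {
  lo <- pmax(apply(hullA$vertices, 2, min), apply(hullB$vertices, 2, min))
  hi <- pmin(apply(hullA$vertices, 2, max), apply(hullB$vertices, 2, max))
  if (any(hi <= lo)) return(0)
  boxVol <- prod(hi - lo)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  pts <- cbind(runif(nSamples, lo[1], hi[1]),
               runif(nSamples, lo[2], hi[2]),
               runif(nSamples, lo[3], hi[3]))
  inBoth <- pointsInHull(hullA, pts) & pointsInHull(hullB, pts)
  boxVol * mean(inBoth)
}
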