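# Bowyer-Watson Delaunay triangulation.
#
# Boundary pixel sets live on the integer grid, where cocircular quadruples
# are everywhere; a tiny deterministic jitter breaks the degeneracy (the
# jittered coordinates are used only for the triangulation topology).

circumcircle <- function(p, tri_idx) {
  a <- p[tri_idx[, 1], , drop = FALSE]
  b <- p[tri_idx[, 2], , drop = FALSE]
  c <- p[tri_idx[, 3], , drop = FALSE]
  d <- 2 * (a[, 1] * (b[, 2] - c[, 2]) + b[, 1] * (c[, 2] - a[, 2]) +
              c[, 1] * (a[, 2] - b[, 2]))
  bad <- abs(d) < 1e-12
  d[bad] <- 1
  a2 <- rowSums(a^2); b2 <- rowSums(b^2); c2 <- rowSums(c^2)
  ux <- (a2 * (b[, 2] - c[, 2]) + b2 * (c[, 2] - a[, 2]) +
           c2 * (a[, 2] - b[, 2])) / d
  uy <- (a2 * (c[, 1] - b[, 1]) + b2 * (a[, 1] - c[, 1]) +
           c2 * (b[, 1] - a[, 1])) / d
  r2 <- (a[, 1] - ux)^2 + (a[, 2] - uy)^2
  r2[bad] <- -Inf                     # collinear: never a "bad" triangle
  cbind(ux, uy, r2)
}

#' Delaunay triangulation of a 2-D point set
#'
#' Incremental Bowyer-Watson construction.  Intended for the boundary-pixel
#' sets used by [smooth_boundary()]; quadratic in the number of points,
#' which is ample for per-lesion boundaries.
#'
#' @param pts `n x 2` numeric matrix of (row, col) coordinates, `n >= 3`.
#' @return Integer `m x 3` matrix of triangle vertex indices into `pts`
#'   (possibly zero rows if all points are collinear).
#' @export
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  # deterministic sub-pixel jitter against cocircular grid points
  j1 <- ((seq_len(n) * 73L) %% 17L - 8L) * 1e-6
  j2 <- ((seq_len(n) * 151L) %% 19L - 9L) * 1e-6
  p <- cbind(pts[, 1] + j1, pts[, 2] + j2)
  # super-triangle far outside the data so its circumcircles approximate
  # half-planes (too close and hull-adjacent triangles are missed)
  mid <- colMeans(p)
  span <- 500 * max(max(p[, 1]) - min(p[, 1]), max(p[, 2]) - min(p[, 2]), 1)
  p <- rbind(p,
             c(mid[1] - 2 * span, mid[2] - span),
             c(mid[1] + 2 * span, mid[2] - span),
             c(mid[1], mid[2] + 2 * span))
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  cc <- circumcircle(p, tri)
  for (i in seq_len(n)) {
    inside <- (p[i, 1] - cc[, 1])^2 + (p[i, 2] - cc[, 2])^2 < cc[, 3]
    if (!any(inside)) next            # degenerate; point skipped
    bad <- tri[inside, , drop = FALSE]
    tri <- tri[!inside, , drop = FALSE]
    cc <- cc[!inside, , drop = FALSE]
    # polygonal hole boundary: edges of bad triangles that appear once
    e <- rbind(bad[, c(1, 2)], bad[, c(2, 3)], bad[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- !(key %in% key[duplicated(key)])
    e <- e[once, , drop = FALSE]
    if (nrow(e) == 0L) next
    newt <- cbind(e[, 1], e[, 2], i)
    tri <- rbind(tri, newt)
    cc <- rbind(cc, circumcircle(p, newt))
  }
  keep <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri[keep, , drop = FALSE]
}

# union of triangles rasterized onto an H x W logical matrix;
# pts are (row, col) coordinates, boundary-inclusive coverage test
rasterize_triangles <- function(tri, pts, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  tol <- 1e-9
  for (t in seq_len(nrow(tri))) {
    v <- pts[tri[t, ], , drop = FALSE]
    r0 <- max(1L, floor(min(v[, 1]))); r1 <- min(shape[1], ceiling(max(v[, 1])))
    c0 <- max(1L, floor(min(v[, 2]))); c1 <- min(shape[2], ceiling(max(v[, 2])))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    pr <- matrix(rr, length(rr), length(cc))
    pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    sgn <- function(p1, p2)
      (pr - p2[1]) * (p1[2] - p2[2]) - (p1[1] - p2[1]) * (pc - p2[2])
    d1 <- sgn(v[1, ], v[2, ]); d2 <- sgn(v[2, ], v[3, ]); d3 <- sgn(v[3, ], v[1, ])
    neg <- d1 < -tol | d2 < -tol | d3 < -tol
    pos <- d1 > tol | d2 > tol | d3 > tol
    out[rr, cc] <- out[rr, cc] | !(neg & pos)
  }
  out
}
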