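# Postprocessing of the evolved lesion mask: hole filling, a fixed
# morphological erosion, and Delaunay-based boundary smoothing.

#' Boundary pixels of a mask
#'
#' A lesion pixel is a boundary pixel when at least one of its 8 neighbors
#' is background (pixels beyond the image edge count as background).
#'
#' @param mask Logical `H x W` matrix.
#' @return `n x 2` integer matrix of (row, col) coordinates.
#' @export
boundary_points <- function(mask) {
  assert_mask(mask)
  interior <- window_filter_cpp(mask * 1, 3L, maximum = FALSE,
                                pad = 0, pad_na = FALSE) > 0.5
  which(mask & !interior, arr.ind = TRUE)
}

#' Fill enclosed holes
#'
#' Flood-fills the mask complement from the image border (4-connectivity on
#' the background); complement components not reachable from the border are
#' enclosed holes and become lesion.  The output is a superset of the
#' input.
#'
#' @param mask Logical `H x W` matrix.
#' @return Logical `H x W` matrix.
#' @export
fill_border_interior <- function(mask) {
  assert_mask(mask)
  if (all(mask)) return(mask)
  lab <- label_components(!mask, 4L)
  H <- nrow(lab); W <- ncol(lab)
  border_ids <- setdiff(unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W])), 0L)
  hole <- !mask & !matrix(lab %in% border_ids, H, W)
  mask | hole
}

#' Morphological erosion by a square structuring element
#'
#' Binary erosion with a `width_px` x `width_px` square; pixels beyond the
#' image edge are treated as background, so a full-image mask shrinks at
#' the borders too.  If the erosion would empty the mask the input is
#' returned unchanged with a warning.
#'
#' @param mask Logical `H x W` matrix.
#' @param width_px Odd structuring-element width (default 5, i.e. 2 px per
#'   side).
#' @return Logical `H x W` matrix, a subset of the input.
#' @export
erode_mask <- function(mask, width_px = 5L) {
  assert_mask(mask)
  stopifnot(width_px >= 1, width_px %% 2 == 1)
  er <- window_filter_cpp(mask * 1, as.integer(width_px), maximum = FALSE,
                          pad = 0, pad_na = FALSE) > 0.5
  if (!any(er)) {
    warning("erosion would empty the mask; returning the input unchanged")
    return(mask)
  }
  er
}

#' Delaunay boundary smoothing
#'
#' Alpha-shape-style regularization: triangulates the boundary pixel set,
#' keeps triangles whose longest edge does not exceed `lmax`, unions their
#' rasterization with the input mask, fills enclosed holes and keeps the
#' largest 8-connected component.  Short-edge triangles bridge cracks and
#' noise-carved concavities while long chords across genuine indentations
#' are discarded; the union with the input keeps the operation conservative
#' (it regularizes the border, it cannot delete the lesion).  Fewer than 3
#' boundary points (or no surviving triangle) returns the input.
#'
#' @param mask Logical `H x W` matrix, non-empty.
#' @param lmax Maximum triangle edge length in pixels (default 30).
#' @return Logical `H x W` matrix.
#' @export
smooth_boundary <- function(mask, lmax = 30) {
  assert_mask(mask)
  pts <- boundary_points(mask)
  if (nrow(pts) < 3L) return(mask)
  tri <- delaunay_triangulate(pts)
  if (nrow(tri) == 0L) return(mask)
  el <- function(i, j) sqrt(rowSums((pts[tri[, i], , drop = FALSE] -
                                       pts[tri[, j], , drop = FALSE])^2))
  keep <- pmax(el(1, 2), el(2, 3), el(3, 1)) <= lmax
  if (!any(keep)) return(mask)
  ras <- rasterize_triangles(tri[keep, , drop = FALSE], pts, dim(mask)) | mask
  ras <- fill_border_interior(ras)
  lab <- label_components(ras, 8L)
  ras & lab == largest_component(lab)
}

#' Final mask cleanup
#'
#' Composition fill -> erode -> smooth -> fill, followed by extraction of
#' the largest 8-connected component, so the result is a single blob (or
#' empty, with a warning, when the input is empty).
#'
#' @param mask Logical `H x W` matrix.
#' @param erode_width Erosion width in pixels (default 5).
#' @param smooth Apply Delaunay boundary smoothing? (default `TRUE`).
#' @param lmax Edge-length cutoff for the smoothing (default 30).
#' @return Logical `H x W` matrix with at most one connected component.
#' @export
finalize_mask <- function(mask, erode_width = 5L, smooth = TRUE, lmax = 30) {
  assert_mask(mask)
  if (!any(mask)) {
    warning("empty mask; nothing to postprocess")
    return(mask)
  }
  m <- fill_border_interior(mask)
  m <- erode_mask(m, erode_width)
  if (smooth) m <- smooth_boundary(m, lmax)
  m <- fill_border_interior(m)
  lab <- label_components(m, 8L)
  if (max(lab) == 0L) return(m)
  m & lab == largest_component(lab)
}
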