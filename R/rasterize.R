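# Even-odd scanline fill for one ring over a grid of voxel centres.
# Classic crossing-number test: an edge is crossed at row y iff
# (y1 > y) != (y2 > y), and toggles columns with xc < x_intersection.
# This makes bottom/left boundaries inclusive and top/right exclusive,
# so abutting rings tile the grid without double-covered voxels.
ring_parity <- function(xy, xc, yc) {
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) {  # closed ring given with repeated vertex
    xy <- xy[-n, , drop = FALSE]
    n <- n - 1L
    if (n < 3L) stop("ring degenerates to fewer than 3 distinct vertices")
  }
  ins <- matrix(FALSE, length(xc), length(yc))
  j <- c(seq_len(n)[-1], 1L)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- xy[j, 1]; y2 <- xy[j, 2]
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next  # horizontal edge never crosses a scanline
    cross <- (y1[e] > yc) != (y2[e] > yc)
    for (row in which(cross)) {
      xint <- x1[e] + (yc[row] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
      hit <- xc < xint
      ins[hit, row] <- !ins[hit, row]
    }
  }
  ins
}

#' Rasterise a planar contour onto a voxel grid
#'
#' Converts an [rt_contour()] into a [binary_mask()]: a voxel is inside iff
#' its centre lies within an odd number of the contour's rings on that
#' voxel's slice (even-odd rule). Each ring is assigned to the nearest slice
#' plane; a ring lying exactly half a slice spacing between two planes is
#' assigned to the lower-index slice, and a ring farther than half a spacing
#' from every plane is an error. Voxel centres exactly on a ring edge follow
#' a half-open convention: bottom/left edges count as inside, top/right as
#' outside.
#'
#' @param contour an [rt_contour()].
#' @param geometry the target [image_geometry()].
#' @return A [binary_mask()].
#' @export
rasterize <- function(contour, geometry) {
  if (!inherits(contour, "rt_contour")) stop("`contour` must be an rt_contour")
  if (!inherits(geometry, "image_geometry"))
    stop("`geometry` must be an image_geometry")
  vox <- array(FALSE, geometry$shape)
  zp <- slice_planes(geometry)
  sz <- geometry$spacing[3]
  xc <- axis_centers(geometry, 1L)
  yc <- axis_centers(geometry, 2L)
  for (ring in contour$rings) {
    dz <- abs(zp - ring$z)
    k <- which.min(dz)  # exact half-spacing tie: which.min takes the lower index
    if (dz[k] > sz / 2 + 1e-9)
      stop(sprintf(
        "ring of '%s' at z = %g mm is farther than half a slice spacing from every slice plane",
        contour$organ_name, ring$z))
    vox[, , k] <- xor(vox[, , k], ring_parity(ring$xy, xc, yc))
  }
  binary_mask(vox, geometry)
}
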