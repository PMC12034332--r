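#' Dice similarity coefficient of two masks
#'
#' Volumetric overlap `2|A n B| / (|A| + |B|)` by voxel count on a shared
#' grid; 1 means identical, 0 disjoint. Symmetric in its arguments.
#'
#' @param a,b [binary_mask()] objects on the same [image_geometry()], at
#'   least one nonempty.
#' @return Dimensionless value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_pair(a, b)
  na <- mask_count(a); nb <- mask_count(b)
  if (na == 0L && nb == 0L)
    stop("DSC undefined: both masks are empty (undefined_empty)")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

check_pair <- function(a, b) {
  if (!inherits(a, "binary_mask") || !inherits(b, "binary_mask"))
    stop("both arguments must be binary_mask objects")
  if (!same_geometry(a$geometry, b$geometry))
    stop("geometry mismatch: masks must share one ImageGeometry")
  invisible(TRUE)
}

#' Extract the boundary-voxel surface of a mask
#'
#' The surface is the set of true voxels having at least one of their six
#' face neighbours false or outside the volume (the volume edge counts as
#' outside). Points are returned as voxel-centre positions in patient mm
#' coordinates; all surface distances in the package are measured between
#' such points.
#'
#' @param m a nonempty [binary_mask()].
#' @return An object of class `surface_points`: an n x 3 mm coordinate
#'   matrix with the source geometry attached.
#' @export
extract_surface <- function(m) {
  if (!inherits(m, "binary_mask")) stop("`m` must be a binary_mask")
  if (mask_is_empty(m)) stop("cannot extract the surface of an empty mask")
  v <- m$voxels
  d <- dim(v)
  interior <- array(TRUE, d)          # all six face neighbours true?
  # x
  nb <- array(FALSE, d); nb[-1, , ] <- v[-d[1], , ]; interior <- interior & nb
  nb <- array(FALSE, d); nb[-d[1], , ] <- v[-1, , ]; interior <- interior & nb
  # y
  nb <- array(FALSE, d); nb[, -1, ] <- v[, -d[2], ]; interior <- interior & nb
  nb <- array(FALSE, d); nb[, -d[2], ] <- v[, -1, ]; interior <- interior & nb
  # z
  nb <- array(FALSE, d); nb[, , -1] <- v[, , -d[3]]; interior <- interior & nb
  nb <- array(FALSE, d); nb[, , -d[3]] <- v[, , -1]; interior <- interior & nb
  surf <- v & !interior
  idx <- which(surf, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, m$geometry$spacing, `*`),
               2, m$geometry$origin, `+`)
  dimnames(pts) <- NULL
  structure(pts, class = "surface_points", geometry = m$geometry)
}

as_point_matrix <- function(s) {
  if (inherits(s, "surface_points")) return(unclass(s))
  if (is.matrix(s) && ncol(s) == 3L) return(s)
  stop("expected a surface_points object or an n x 3 coordinate matrix")
}

directed_dists <- function(a, b) nn_min_dists(a, b)

#' Maximum Hausdorff distance between two surfaces
#'
#' The symmetric maximum over both directed maxima: the largest
#' nearest-point distance from either surface to the other, Euclidean in
#' mm. This is the full maximum, not a percentile variant — the screening
#' thresholds (one slice, 2 mm) are only meaningful for the maximum.
#'
#' @param sa,sb nonempty [extract_surface()] point sets (or n x 3 mm
#'   matrices).
#' @return Distance in mm.
#' @export
hausdorff_max <- function(sa, sb) {
  a <- as_point_matrix(sa); b <- as_point_matrix(sb)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("Hausdorff distance requires two nonempty surfaces")
  max(max(directed_dists(a, b)), max(directed_dists(b, a)))
}

#' Mean distance to agreement between two surfaces
#'
#' Pooled symmetric average surface distance: the sum of all nearest-point
#' distances in both directions divided by the total number of surface
#' points, `(sum_a d(p, Sb) + sum_b d(q, Sa)) / (|Sa| + |Sb|)`. The
#' alternative convention (mean of the two directed averages) is a
#' one-line variant of this function; the pooled form is used throughout.
#'
#' @param sa,sb nonempty [extract_surface()] point sets (or n x 3 mm
#'   matrices).
#' @return Distance in mm.
#' @export
mean_distance_to_agreement <- function(sa, sb) {
  a <- as_point_matrix(sa); b <- as_point_matrix(sb)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("MDTA requires two nonempty surfaces")
  (sum(directed_dists(a, b)) + sum(directed_dists(b, a))) / (nrow(a) + nrow(b))
}

#' Compute the (DSC, MDTA, HD) metric triple for a mask pair
#'
#' Bundles the three geometric indices used for version screening. If
#' either mask is empty the triple is reported with status
#' `"undefined_empty"` and `NA` values rather than fabricated numbers — a
#' vanished organ is the most severe modification and must surface
#' explicitly downstream.
#'
#' @param a,b [binary_mask()] objects on the same geometry.
#' @return An object of class `metric_triple` with fields `dsc`, `mdta_mm`,
#'   `hd_mm` and `status` (`"computed"` or `"undefined_empty"`).
#' @export
metric_triple <- function(a, b) {
  check_pair(a, b)
  if (mask_is_empty(a) || mask_is_empty(b)) {
    return(structure(list(dsc = NA_real_, mdta_mm = NA_real_,
                          hd_mm = NA_real_, status = "undefined_empty"),
                     class = "metric_triple"))
  }
  if (identical(a$voxels, b$voxels)) {  # exact: identical masks need no search
    return(structure(list(dsc = 1, mdta_mm = 0, hd_mm = 0,
                          status = "computed"),
                     class = "metric_triple"))
  }
  sa <- as_point_matrix(extract_surface(a))
  sb <- as_point_matrix(extract_surface(b))
  dab <- directed_dists(sa, sb)  # each direction computed once, used by both
  dba <- directed_dists(sb, sa)
  structure(list(dsc = dice(a, b),
                 mdta_mm = (sum(dab) + sum(dba)) / (nrow(sa) + nrow(sb)),
                 hd_mm = max(max(dab), max(dba)),
                 status = "computed"),
            class = "metric_triple")
}

#' @export
print.metric_triple <- function(x, ...) {
  if (x$status == "computed")
    cat(sprintf("<metric_triple> DSC %.4f, MDTA %.3f mm, HD %.3f mm\n",
                x$dsc, x$mdta_mm, x$hd_mm))
  else cat("<metric_triple> undefined_empty (at least one mask empty)\n")
  invisible(x)
}
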