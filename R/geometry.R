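#' Image geometry of a CT voxel grid
#'
#' Describes the voxel lattice every structure in a patient's structure sets
#' is referenced to: voxel counts, physical spacing, and the patient-space
#' position of the first voxel centre. All physical quantities are in mm and
#' all distances computed by the package derive from this object, so two
#' masks can only be compared when they share one geometry. Only
#' constant-slice-spacing grids are representable; the slice spacing is the
#' third component of `spacing`.
#'
#' @param shape integer vector of length 3: voxel counts (nx, ny, nz).
#' @param spacing numeric vector of length 3: mm per voxel along x, y, z.
#'   All components must be strictly positive.
#' @param origin numeric vector of length 3: mm position, in the patient
#'   coordinate frame, of the centre of voxel (1, 1, 1). Defaults to the
#'   frame origin.
#' @param axis_convention tag for the fixed patient-coordinate frame.
#' @return An object of class `image_geometry`.
#' @examples
#' geom <- image_geometry(c(64, 64, 30), spacing = c(1, 1, 2))
#' slice_planes(geom)[1:3]
#' @export
image_geometry <- function(shape, spacing, origin = c(0, 0, 0),
                           axis_convention = "LPS") {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive voxel counts")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be strictly positive")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite mm coordinates")
  structure(
    list(shape = shape, spacing = spacing, origin = origin,
         axis_convention = as.character(axis_convention)),
    class = "image_geometry"
  )
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
format.image_geometry <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g)mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Voxel-centre coordinates along one axis
#'
#' @param geometry an [image_geometry()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of mm coordinates of voxel centres along the axis.
#' @export
axis_centers <- function(geometry, axis) {
  geometry$origin[axis] +
    (seq_len(geometry$shape[axis]) - 1) * geometry$spacing[axis]
}

#' Z coordinates of the slice planes
#'
#' @param geometry an [image_geometry()].
#' @return Numeric vector: mm z position of every transverse slice plane.
#' @export
slice_planes <- function(geometry) axis_centers(geometry, 3L)

#' Binary voxel mask of one structure
#'
#' The rasterised form of an organ contour: a 3-D logical array on an
#' [image_geometry()] grid, `TRUE` inside the structure. Empty masks (zero
#' true voxels) are representable; metric code must branch on them
#' explicitly rather than fabricate numbers.
#'
#' @param voxels logical 3-D array whose dimensions equal `geometry$shape`.
#' @param geometry the [image_geometry()] the voxels live on.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, geometry) {
  if (!inherits(geometry, "image_geometry"))
    stop("`geometry` must be an image_geometry")
  if (is.null(dim(voxels)) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  if (!identical(as.integer(dim(voxels)), geometry$shape))
    stop("mask shape does not equal geometry shape")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  structure(list(voxels = voxels, geometry = geometry),
            class = "binary_mask")
}

#' All-false mask on a grid
#'
#' @param geometry an [image_geometry()].
#' @return An empty [binary_mask()].
#' @export
empty_mask <- function(geometry) {
  binary_mask(array(FALSE, geometry$shape), geometry)
}

#' Number of true voxels in a mask
#'
#' @param m a [binary_mask()].
#' @return Integer voxel count.
#' @export
mask_count <- function(m) sum(m$voxels)

#' Is a mask empty?
#'
#' @param m a [binary_mask()].
#' @return `TRUE` if the mask has no true voxel.
#' @export
mask_is_empty <- function(m) !any(m$voxels)

#' Physical volume of a mask
#'
#' @param m a [binary_mask()].
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume_mm3 <- function(m) mask_count(m) * prod(m$geometry$spacing)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %d true voxels\n",
              format(x$geometry), mask_count(x)))
  invisible(x)
}

#' Planar contour of one organ
#'
#' A named organ delineation as a list of closed planar rings in patient mm
#' coordinates, each ring at a fixed z. Several rings may share one slice:
#' disjoint in-plane regions (e.g. an isolated mis-segmented island) are
#' representable, and overlapping rings combine by the even-odd rule at
#' rasterisation.
#'
#' @param organ_name name of the organ.
#' @param rings list of rings; each ring is a list with `z` (mm, scalar) and
#'   `xy` (n x 2 numeric matrix of vertices, n >= 3, not repeating the first
#'   vertex).
#' @return An object of class `rt_contour`.
#' @export
rt_contour <- function(organ_name, rings) {
  if (!is.character(organ_name) || length(organ_name) != 1L || !nzchar(organ_name))
    stop("`organ_name` must be a single non-empty string")
  for (r in rings) {
    if (is.null(r$xy) || is.null(r$z))
      stop("each ring needs `xy` vertices and a `z` plane")
    if (!is.matrix(r$xy) || ncol(r$xy) != 2L || nrow(r$xy) < 3L)
      stop("each ring must have >= 3 vertices in an n x 2 matrix")
    if (length(r$z) != 1L || !is.finite(r$z))
      stop("ring `z` must be a single finite mm coordinate")
  }
  structure(list(organ_name = organ_name, rings = rings),
            class = "rt_contour")
}

#' Structure set: all organ masks for one patient under one version label
#'
#' Groups the delineations produced by one software version (or the expert
#' ground truth) for one patient. Every structure references the same
#' [image_geometry()]; organ names are unique within the set. Structures may
#' be [binary_mask()]s or [rt_contour()]s (rasterised on demand).
#'
#' @param patient_id patient identifier.
#' @param version_label version tag, e.g. `"old"`, `"new"`, `"ground_truth"`.
#' @param structures named list of [binary_mask()] or [rt_contour()] objects;
#'   names are the organ names.
#' @param geometry the common [image_geometry()].
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(patient_id, version_label, structures, geometry) {
  if (!inherits(geometry, "image_geometry"))
    stop("`geometry` must be an image_geometry")
  nm <- names(structures)
  if (length(structures) > 0 && (is.null(nm) || any(!nzchar(nm))))
    stop("`structures` must be a named list")
  if (anyDuplicated(nm))
    stop("duplicate organ names in structure set: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (s in structures) {
    if (inherits(s, "binary_mask")) {
      if (!same_geometry(s$geometry, geometry))
        stop("all structures must reference one ImageGeometry")
    } else if (!inherits(s, "rt_contour")) {
      stop("structures must be binary_mask or rt_contour objects")
    }
  }
  structure(
    list(patient_id = as.character(patient_id),
         version_label = as.character(version_label),
         structures = structures, geometry = geometry),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> patient %s, version %s, %d structures (%s)\n",
              x$patient_id, x$version_label, length(x$structures),
              format(x$geometry)))
  invisible(x)
}

#' Fetch one structure as a mask
#'
#' Returns the named structure of a set as a [binary_mask()], rasterising a
#' planar contour if necessary. Returns `NULL` if the organ is absent.
#'
#' @param ss a [structure_set()].
#' @param organ organ name.
#' @return A [binary_mask()] or `NULL`.
#' @export
get_mask <- function(ss, organ) {
  s <- ss$structures[[organ]]
  if (is.null(s)) return(NULL)
  if (inherits(s, "binary_mask")) return(s)
  rasterize(s, ss$geometry)
}
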