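geometry_to_list <- function(g) {
  list(shape = g$shape, spacing_mm = g$spacing, origin_mm = g$origin,
       axis_convention = g$axis_convention)
}

geometry_from_list <- function(x) {
  image_geometry(unlist(x$shape), unlist(x$spacing_mm), unlist(x$origin_mm),
                 if (is.null(x$axis_convention)) "LPS" else x$axis_convention)
}

safe_file_name <- function(organ) gsub("[^A-Za-z0-9._-]+", "_", organ)

write_mask_nifti <- function(voxels, geometry, file, datatype = "uint8") {
  arr <- array(as.integer(voxels), dim = dim(voxels))
  attr(arr, "pixdim") <- geometry$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), file)
}

read_mask_nifti <- function(file) {
  arr <- as.array(RNifti::readNifti(file))
  if (length(dim(arr)) != 3L) stop("mask volume in ", file, " is not 3-D")
  arr
}

#' Write a structure set to disk
#'
#' Two on-disk layouts are supported, both NIfTI volumes with a JSON
#' sidecar carrying the authoritative geometry and organ names:
#'
#' * `"dir"` (canonical): a directory holding `structure_set.json` plus one
#'   binary NIfTI mask per organ. Structures may overlap; empty structures
#'   are written as all-zero volumes, never dropped.
#' * `"labelmap"`: a single integer label volume `masks.nii.gz` with sidecar
#'   `masks.json` mapping label integers to organ names. Only valid when
#'   structures are pairwise disjoint.
#'
#' Both layouts round-trip bit-exactly through [read_structure_set()].
#'
#' @param ss a [structure_set()]; planar contours are rasterised on write.
#' @param path output directory (created if needed).
#' @param format `"dir"` or `"labelmap"`.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(ss, path, format = c("dir", "labelmap")) {
  format <- match.arg(format)
  if (!inherits(ss, "structure_set")) stop("`ss` must be a structure_set")
  if (anyDuplicated(names(ss$structures)))
    stop("duplicate organ names; refusing to write")
  masks <- lapply(names(ss$structures), function(o) get_mask(ss, o))
  names(masks) <- names(ss$structures)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory ", path)

  if (format == "dir") {
    files <- vapply(names(masks),
                    function(o) paste0(safe_file_name(o), ".nii.gz"),
                    character(1))
    if (anyDuplicated(files))
      stop("organ names collide after file-name sanitisation")
    for (o in names(masks))
      write_mask_nifti(masks[[o]]$voxels, ss$geometry,
                       file.path(path, files[[o]]))
    meta <- list(patient_id = ss$patient_id,
                 version_label = ss$version_label,
                 geometry = geometry_to_list(ss$geometry),
                 structures = as.list(files))
    jsonlite::write_json(meta, file.path(path, "structure_set.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    counts <- Reduce(`+`, lapply(masks, function(m) m$voxels + 0L),
                     array(0L, ss$geometry$shape))
    if (any(counts > 1L))
      stop("structures overlap; the labelmap format requires disjoint masks")
    lab <- array(0L, ss$geometry$shape)
    labels <- list()
    for (i in seq_along(masks)) {
      lab[masks[[i]]$voxels] <- i
      labels[[as.character(i)]] <- names(masks)[i]
    }
    write_mask_nifti(lab, ss$geometry, file.path(path, "masks.nii.gz"),
                     datatype = "int16")
    meta <- list(patient_id = ss$patient_id,
                 version_label = ss$version_label,
                 geometry = geometry_to_list(ss$geometry),
                 labels = labels, volume = "masks.nii.gz")
    jsonlite::write_json(meta, file.path(path, "masks.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a structure set from disk
#'
#' Accepts either layout written by [write_structure_set()]: a directory
#' containing `structure_set.json` (one mask volume per organ), or a label
#' volume with a JSON sidecar mapping label integers to organ names. Organ
#' names are passed through verbatim; canonicalisation is the pairing
#' step's job. A structure whose volume contains no voxels is included as
#' an empty mask with a warning, never dropped.
#'
#' @param path directory (dir layout) or the label-volume / sidecar file
#'   (labelmap layout).
#' @param geometry_source optional [image_geometry()] used when the sidecar
#'   carries no geometry block; if both are absent the read fails.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(path, geometry_source = NULL) {
  if (dir.exists(path) && file.exists(file.path(path, "structure_set.json"))) {
    meta <- jsonlite::read_json(file.path(path, "structure_set.json"))
    geom <- resolve_geometry(meta, geometry_source, path)
    structures <- list()
    for (o in names(meta$structures)) {
      f <- file.path(path, meta$structures[[o]])
      if (!file.exists(f)) stop("missing mask volume for organ ", o, ": ", f)
      arr <- read_mask_nifti(f)
      if (!identical(as.integer(dim(arr)), geom$shape))
        stop("mask volume for ", o, " does not match the declared geometry")
      m <- binary_mask(arr != 0L, geom)
      if (mask_is_empty(m))
        warning("structure '", o, "' is empty in ", path, call. = FALSE)
      structures[[o]] <- m
    }
    return(structure_set(meta$patient_id, meta$version_label, structures, geom))
  }

  # labelmap layout: accept the volume or its sidecar
  sidecar <- if (grepl("\\.json$", path)) path else
    sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop("no structure set at ", path, " (sidecar ", sidecar, " not found)")
  meta <- jsonlite::read_json(sidecar)
  vol_file <- file.path(dirname(sidecar),
                        if (is.null(meta$volume)) basename(sub("\\.json$", ".nii.gz", sidecar))
                        else meta$volume)
  if (!file.exists(vol_file)) stop("label volume not found: ", vol_file)
  geom <- resolve_geometry(meta, geometry_source, path)
  lab <- read_mask_nifti(vol_file)
  if (!identical(as.integer(dim(lab)), geom$shape))
    stop("label volume does not match the declared geometry")
  if (is.null(meta$labels) || length(meta$labels) == 0L)
    stop("sidecar ", sidecar, " declares no labels")
  structures <- list()
  for (li in names(meta$labels)) {
    o <- meta$labels[[li]]
    m <- binary_mask(lab == as.integer(li), geom)
    if (mask_is_empty(m))
      warning("structure '", o, "' is empty in ", path, call. = FALSE)
    structures[[o]] <- m
  }
  structure_set(meta$patient_id, meta$version_label, structures, geom)
}

resolve_geometry <- function(meta, geometry_source, path) {
  if (!is.null(meta$geometry)) return(geometry_from_list(meta$geometry))
  if (inherits(geometry_source, "image_geometry")) return(geometry_source)
  if (is.character(geometry_source) && file.exists(geometry_source))
    return(geometry_from_list(jsonlite::read_json(geometry_source)))
  stop("missing geometry: ", path,
       " has no geometry block and no geometry_source was supplied")
}

#' Read a cohort of structure sets from a directory
#'
#' Reads every structure-set subdirectory of `path` (dir layout) in sorted
#' order, one per patient.
#'
#' @param path directory whose subdirectories are structure sets.
#' @return List of [structure_set()] objects.
#' @export
read_cohort <- function(path) {
  subs <- sort(list.dirs(path, recursive = FALSE))
  subs <- subs[file.exists(file.path(subs, "structure_set.json"))]
  if (length(subs) == 0L) stop("no structure sets found under ", path)
  lapply(subs, read_structure_set)
}

#' Write a cohort of structure sets
#'
#' One subdirectory per patient, named by patient id.
#'
#' @param sets list of [structure_set()] objects.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sets, path) {
  for (ss in sets)
    write_structure_set(ss, file.path(path, safe_file_name(ss$patient_id)))
  invisible(path)
}
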