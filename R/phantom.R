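#' Primitive organ shape specification
#'
#' Phantom organs are analytic primitives rasterised by voxel-centre
#' containment, so their volumes and mutual distances are known in closed
#' form and every downstream metric can be checked against arithmetic.
#'
#' @param name organ name (canonical, lower case).
#' @param shape `"sphere"`, `"ellipsoid"`, `"tube"` (cylinder along z) or
#'   `"box"`.
#' @param center mm centre (x, y, z).
#' @param size shape size in mm: sphere radius (scalar); ellipsoid radii
#'   (length 3); tube `c(radius, z_length)`; box full edge lengths
#'   (length 3).
#' @return An object of class `organ_shape`.
#' @export
organ_shape <- function(name, shape = c("sphere", "ellipsoid", "tube", "box"),
                        center, size) {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  size <- as.numeric(size)
  if (length(center) != 3L) stop("`center` must be (x, y, z) in mm")
  need <- c(sphere = 1L, ellipsoid = 3L, tube = 2L, box = 3L)[[shape]]
  if (length(size) != need)
    stop(sprintf("shape '%s' needs %d size value(s)", shape, need))
  if (any(size <= 0)) stop("all size values must be positive")
  structure(list(name = tolower(name), shape = shape,
                 center = center, size = size),
            class = "organ_shape")
}

shape_half_extent <- function(org) {
  switch(org$shape,
         sphere = rep(org$size[1], 3),
         ellipsoid = org$size,
         tube = c(org$size[1], org$size[1], org$size[2] / 2),
         box = org$size / 2)
}

make_shape_mask <- function(org, geometry, offset = c(0, 0, 0)) {
  ctr <- org$center + offset
  lo <- geometry$origin - geometry$spacing / 2
  hi <- geometry$origin + (geometry$shape - 1) * geometry$spacing +
    geometry$spacing / 2
  ext <- shape_half_extent(org)
  if (any(ctr - ext < lo) || any(ctr + ext > hi))
    stop("organ '", org$name, "' escapes the volume after jitter")
  xc <- axis_centers(geometry, 1L) - ctr[1]
  yc <- axis_centers(geometry, 2L) - ctr[2]
  zc <- axis_centers(geometry, 3L) - ctr[3]
  vox <- switch(org$shape,
    sphere = outer(outer(xc^2, yc^2, `+`), zc^2, `+`) <= org$size[1]^2,
    ellipsoid = outer(outer((xc / org$size[1])^2, (yc / org$size[2])^2, `+`),
                      (zc / org$size[3])^2, `+`) <= 1,
    tube = outer(outer(xc^2, yc^2, `+`) <= org$size[1]^2,
                 abs(zc) <= org$size[2] / 2, `&`),
    box = outer(outer(abs(xc) <= org$size[1] / 2,
                      abs(yc) <= org$size[2] / 2, `&`),
                abs(zc) <= org$size[3] / 2, `&`))
  binary_mask(vox, geometry)
}

#' Default phantom organ layout
#'
#' A compact pelvis-plus-cranium layout of eight analytic organs sized so
#' that the characteristic update failure modes are all expressible:
#' brain/brainstem overlap for carve tests, a prostate-adjacent rectum
#' tube for crop and truncation tests, small lens/optic-nerve bodies for
#' one-slice-extension tests, and a bladder for whole-organ shifts.
#'
#' @return List of [organ_shape()] objects.
#' @export
default_phantom_organs <- function() {
  list(
    organ_shape("brain", "sphere", c(30, 30, 90), 20),
    organ_shape("brainstem", "tube", c(30, 30, 75), c(6, 40)),
    organ_shape("lens_right", "ellipsoid", c(70, 20, 100), c(3, 3, 6)),
    organ_shape("optic_nerve_right", "ellipsoid", c(70, 35, 95), c(2.5, 2.5, 7)),
    organ_shape("prostate", "sphere", c(60, 60, 45), 12),
    organ_shape("rectum", "tube", c(60, 80, 60), c(9, 60)),
    organ_shape("bladder", "ellipsoid", c(60, 35, 55), c(14, 12, 10)),
    organ_shape("seminal_vesicle", "ellipsoid", c(82, 60, 62), c(6, 5, 6))
  )
}

#' Phantom cohort specification
#'
#' Defines a synthetic cohort: a voxel grid (default 96 x 96 x 60 at
#' (1, 1, 2) mm, the 2 mm slice thickness of a typical planning CT
#' protocol), an organ layout, a patient count and a per-patient jitter
#' scale. Identical (spec, seed) pairs generate bit-identical cohorts.
#'
#' @param n_patients number of patients.
#' @param seed integer seed governing all jitter.
#' @param geometry an [image_geometry()].
#' @param organs list of [organ_shape()] objects.
#' @param inter_patient_jitter_mm uniform jitter half-width applied to
#'   every organ centre, per patient and axis.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 25, seed = 1,
                         geometry = image_geometry(c(96, 96, 60), c(1, 1, 2)),
                         organs = default_phantom_organs(),
                         inter_patient_jitter_mm = 2) {
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (inter_patient_jitter_mm < 0) stop("jitter must be >= 0")
  nm <- vapply(organs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate organ names in phantom spec")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 geometry = geometry, organs = organs,
                 inter_patient_jitter_mm = inter_patient_jitter_mm),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate the ground-truth cohort of a phantom spec
#'
#' Draws one centre jitter per patient, organ and axis (uniform in
#' `+-inter_patient_jitter_mm`) from the spec seed in a fixed order, so
#' the cohort is reproducible bit-exactly. An organ pushed outside the
#' volume by its jitter is an error naming the organ.
#'
#' @param spec a [phantom_spec()].
#' @param version_label label of the generated sets (default
#'   `"ground_truth"`).
#' @return List of [structure_set()] objects, one per patient.
#' @export
generate_cohort <- function(spec, version_label = "ground_truth") {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  norg <- length(spec$organs)
  jit <- with_seed(spec$seed, {
    array(stats::runif(spec$n_patients * norg * 3,
                       -spec$inter_patient_jitter_mm,
                       spec$inter_patient_jitter_mm),
          dim = c(3, norg, spec$n_patients))
  })
  lapply(seq_len(spec$n_patients), function(i) {
    structures <- lapply(seq_len(norg), function(k)
      make_shape_mask(spec$organs[[k]], spec$geometry, jit[, k, i]))
    names(structures) <- vapply(spec$organs, `[[`, "", "name")
    structure_set(sprintf("P%03d", i), version_label, structures,
                  spec$geometry)
  })
}

#' Perturbation specification for the updated version
#'
#' Each kind models a failure mode observed when segmentation software is
#' updated: `extend_slices` (a contour grown by whole slices at one end),
#' `truncate_slices` (a contour shortened at one end), `add_isolated_blob`
#' (a spurious disconnected region far from the organ), `carve_overlap`
#' (an overlap with a neighbouring organ newly excluded), plus generic
#' `translate`, `dilate`, `erode` and `none`.
#'
#' @param organ organ to perturb.
#' @param kind one of `"none"`, `"translate"`, `"dilate"`, `"erode"`,
#'   `"truncate_slices"`, `"extend_slices"`, `"add_isolated_blob"`,
#'   `"carve_overlap"`.
#' @param magnitude mm for `translate`; morphological iterations (voxels)
#'   for `dilate`/`erode`; slice count for `truncate_slices` /
#'   `extend_slices`.
#' @param axis translation axis, `"x"`, `"y"` or `"z"`.
#' @param end `"superior"` or `"inferior"` for slice operations.
#' @param offset_mm blob centre offset from the organ centroid (length 3).
#' @param blob_radius_mm blob radius.
#' @param other_organ organ whose mask is subtracted by `carve_overlap`.
#' @param probability fraction of patients affected, in `[0, 1]`.
#' @param seed seed selecting the affected patient subset.
#' @param patients optional explicit patient indices, overriding the
#'   seeded draw.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation <- function(organ,
                         kind = c("none", "translate", "dilate", "erode",
                                  "truncate_slices", "extend_slices",
                                  "add_isolated_blob", "carve_overlap"),
                         magnitude = 0, axis = "x",
                         end = c("superior", "inferior"),
                         offset_mm = NULL, blob_radius_mm = 4,
                         other_organ = NULL,
                         probability = 1, seed = 1, patients = NULL) {
  kind <- match.arg(kind)
  end <- match.arg(end)
  if (probability < 0 || probability > 1) stop("probability must be in [0, 1]")
  if (kind == "add_isolated_blob" &&
      (is.null(offset_mm) || length(offset_mm) != 3L))
    stop("add_isolated_blob requires a length-3 `offset_mm`")
  if (kind == "carve_overlap" && is.null(other_organ))
    stop("carve_overlap requires `other_organ`")
  structure(list(organ = tolower(organ), kind = kind, magnitude = magnitude,
                 axis = axis, end = end, offset_mm = offset_mm,
                 blob_radius_mm = blob_radius_mm,
                 other_organ = if (is.null(other_organ)) NULL
                   else tolower(other_organ),
                 probability = probability, seed = as.integer(seed),
                 patients = patients),
            class = "perturbation_spec")
}

shift_voxels <- function(v, axis, k) {
  if (k == 0L) return(v)
  d <- dim(v)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(k) >= n) stop("translation exceeds the volume")
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  idx_src <- list(quote(expr =), quote(expr =), quote(expr =))
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  lost <- do.call(`[`, c(list(v), {
    i <- list(quote(expr =), quote(expr =), quote(expr =))
    i[[axis]] <- if (k > 0) (n - k + 1):n else 1:(-k)
    i
  }))
  if (any(lost)) stop("organ escapes the volume under translation")
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(v), idx_src)))))
}

dilate6 <- function(v, k) {
  for (i in seq_len(k)) {
    out <- v
    for (ax in 1:3) {
      out <- out | shift_lossy(v, ax, 1L) | shift_lossy(v, ax, -1L)
    }
    v <- out
  }
  v
}

erode6 <- function(v, k) {
  for (i in seq_len(k)) {
    out <- v
    for (ax in 1:3) {
      out <- out & shift_lossy(v, ax, 1L, fill = FALSE) &
        shift_lossy(v, ax, -1L, fill = FALSE)
    }
    v <- out
  }
  v
}

# shift that silently drops voxels pushed over the edge (morphology helper)
shift_lossy <- function(v, axis, k, fill = FALSE) {
  d <- dim(v)
  out <- array(fill, d)
  n <- d[axis]
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  idx <- list(quote(expr =), quote(expr =), quote(expr =))
  idx_dst <- idx; idx_dst[[axis]] <- dst
  idx_src <- idx; idx_src[[axis]] <- src
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(v), idx_src)))))
}

occupied_slices <- function(v) which(apply(v, 3, any))

mask_centroid_mm <- function(m) {
  idx <- which(m$voxels, arr.ind = TRUE)
  colMeans(sweep(sweep(idx - 1, 2, m$geometry$spacing, `*`),
                 2, m$geometry$origin, `+`))
}

apply_one_perturbation <- function(mask, p, geometry, others) {
  v <- mask$voxels
  switch(p$kind,
    none = mask,
    translate = {
      ax <- match(p$axis, c("x", "y", "z"))
      k <- round(p$magnitude / geometry$spacing[ax])
      if (k == 0 && p$magnitude != 0) k <- sign(p$magnitude)  # at least one voxel
      binary_mask(shift_voxels(v, ax, as.integer(k)), geometry)
    },
    dilate = binary_mask(dilate6(v, as.integer(p$magnitude)), geometry),
    erode = binary_mask(erode6(v, as.integer(p$magnitude)), geometry),
    truncate_slices = {
      occ <- occupied_slices(v)
      k <- as.integer(p$magnitude)
      if (k >= length(occ))
        stop("truncation of ", k, " slices >= organ slice count (",
             length(occ), ") for '", p$organ, "'")
      drop <- if (p$end == "inferior") occ[seq_len(k)]
        else occ[length(occ) - seq_len(k) + 1L]
      v[, , drop] <- FALSE
      binary_mask(v, geometry)
    },
    extend_slices = {
      occ <- occupied_slices(v)
      k <- as.integer(p$magnitude)
      t <- if (p$end == "superior") occ[length(occ)] else occ[1]
      tgt <- if (p$end == "superior") t + seq_len(k) else t - seq_len(k)
      if (any(tgt < 1L | tgt > dim(v)[3]))
        stop("extension leaves the volume for '", p$organ, "'")
      for (s in tgt) v[, , s] <- v[, , t]
      binary_mask(v, geometry)
    },
    add_isolated_blob = {
      ctr <- mask_centroid_mm(mask) + p$offset_mm
      blob <- make_shape_mask(
        organ_shape(paste0(p$organ, "_blob"), "sphere", ctr,
                    p$blob_radius_mm),
        geometry)
      if (mask_is_empty(blob)) stop("blob contains no voxels")
      if (any(blob$voxels & v))
        stop("blob overlaps '", p$organ, "'; it must be an isolated region")
      binary_mask(v | blob$voxels, geometry)
    },
    carve_overlap = {
      other <- others[[p$other_organ]]
      if (is.null(other))
        stop("carve_overlap: organ '", p$other_organ, "' absent")
      binary_mask(v & !other$voxels, geometry)
    })
}

#' Apply version perturbations to a cohort
#'
#' Produces the "updated software" version of a cohort: each perturbation
#' selects its affected patients deterministically from its own seed
#' (or an explicit `patients` vector) and edits that organ's mask.
#' Perturbations are applied in list order, so several can compound on one
#' organ. Unperturbed organs are carried over bit-identically.
#'
#' @param cohort list of [structure_set()] objects (the source version).
#' @param perturbations list of [perturbation()] specs.
#' @param new_label version label of the returned sets.
#' @return List of [structure_set()] objects.
#' @export
apply_perturbations <- function(cohort, perturbations, new_label = "new") {
  n <- length(cohort)
  organs_present <- names(cohort[[1]]$structures)
  for (p in perturbations)
    if (!(p$organ %in% organs_present))
      stop("perturbation organ '", p$organ, "' not present in the cohort")
  out <- lapply(cohort, function(ss)
    structure_set(ss$patient_id, new_label, ss$structures, ss$geometry))
  for (p in perturbations) {
    affected <- if (!is.null(p$patients)) as.integer(p$patients)
      else with_seed(p$seed, which(stats::runif(n) < p$probability))
    for (i in affected) {
      out[[i]]$structures[[p$organ]] <- apply_one_perturbation(
        out[[i]]$structures[[p$organ]], p, cohort[[i]]$geometry,
        cohort[[i]]$structures)
    }
  }
  out
}

#' Bundled three-version fixture with a flag manifest
#'
#' Builds an `old` / `new` / `ground_truth` cohort whose perturbations
#' mirror the characteristic update failure modes: the brain carved by the
#' brainstem overlap, the rectum systematically truncated inferiorly plus
#' one patient with an isolated far blob, the lens and optic nerve
#' extended by a single slice, and the bladder shifted bodily by one
#' in-plane voxel. The pre-update version equals the ground truth (the
#' pre-update model is taken as previously validated), so every geometric
#' change is attributable to the simulated update.
#'
#' The fixture uses a 2.5 mm slice spacing so that a one-slice extension
#' (2.5 mm) strictly exceeds the 2 mm strict-criteria HD threshold —
#' values exactly at a threshold do not violate — while staying far below
#' the 10 mm standard threshold.
#'
#' The returned manifest lists the organs that MUST be flagged under the
#' strict criteria (A), the organs that must not be, and the organ whose
#' systematic truncation should reach significance in the ground-truth
#' re-evaluation.
#'
#' @param seed integer seed for jitter and patient selection.
#' @param n_patients cohort size (default 25).
#' @return List: `sets` (named list of cohorts `old`, `new`,
#'   `ground_truth`), `manifest`, `crop_rules`, `geometry`.
#' @export
scenario_update_qa <- function(seed = 1, n_patients = 25) {
  geom <- image_geometry(c(96, 96, 48), c(1, 1, 2.5))
  spec <- phantom_spec(n_patients = n_patients, seed = seed,
                       geometry = geom, organs = default_phantom_organs(),
                       inter_patient_jitter_mm = 2)
  gt <- generate_cohort(spec, version_label = "ground_truth")
  old <- lapply(gt, function(ss)
    structure_set(ss$patient_id, "old", ss$structures, ss$geometry))
  perts <- list(
    perturbation("brain", "carve_overlap", other_organ = "brainstem",
                 probability = 1, seed = seed + 11L),
    perturbation("rectum", "truncate_slices", magnitude = 2,
                 end = "inferior", probability = 1, seed = seed + 12L),
    perturbation("rectum", "add_isolated_blob", offset_mm = c(0, -40, 0),
                 blob_radius_mm = 4, patients = 1L, seed = seed + 13L),
    perturbation("lens_right", "extend_slices", magnitude = 1,
                 end = "superior", probability = 1, seed = seed + 14L),
    perturbation("optic_nerve_right", "extend_slices", magnitude = 1,
                 end = "superior", probability = 1, seed = seed + 15L),
    perturbation("bladder", "translate", magnitude = 1, axis = "x",
                 probability = 1, seed = seed + 16L))
  new <- apply_perturbations(gt, perts, new_label = "new")
  manifest <- list(
    must_flag_A = sort(c("brain", "rectum", "lens_right",
                         "optic_nerve_right", "bladder")),
    must_not_flag_A = sort(c("brainstem", "prostate", "seminal_vesicle")),
    truncated_organ = "rectum",
    truncated_metric = "hd",
    blob_patient = "P001")
  list(sets = list(old = old, new = new, ground_truth = gt),
       manifest = manifest, crop_rules = default_crop_rules(),
       geometry = geom, perturbations = perts)
}
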