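#' Canonical organ inventory
#'
#' The 28-organ inventory covering head and neck, chest, abdomen and
#' pelvis that the screening method is designed around, as shipped in
#' `extdata/organ_inventory.csv`. Extensible: pairing accepts any organ
#' name, but names outside the inventory are reported as unknown.
#'
#' @return Data frame with columns `organ` and `region`.
#' @export
organ_inventory <- function() {
  f <- system.file("extdata", "organ_inventory.csv", package = "segqa",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

canonical_name <- function(raw, name_map) {
  mapped <- if (!is.null(name_map) && raw %in% names(name_map))
    name_map[[raw]] else raw
  tolower(mapped)
}

#' Pair structures across versions
#'
#' Groups a list of structure sets by patient and canonical organ name,
#' producing one pairing per patient x organ present in at least one
#' version. Raw names are first passed through `name_map` (raw ->
#' canonical), then matched case-insensitively. Organs absent from some
#' version are recorded in `missing_in` — such pairings are excluded from
#' metric computation but kept so reports can show inventory drift between
#' software versions. Names outside the declared inventory pass through
#' and are listed in the `unknown_organs` attribute, never dropped.
#'
#' @param sets list of [structure_set()] objects (multiple patients and
#'   version labels).
#' @param name_map optional named character vector or list, raw name ->
#'   canonical name.
#' @param inventory character vector of known canonical names; defaults to
#'   [organ_inventory()].
#' @return List of `organ_pairing` objects (patient_id, organ_name, masks
#'   per version, missing_in), with attributes `versions` and
#'   `unknown_organs`.
#' @export
match_structures <- function(sets, name_map = NULL, inventory = NULL) {
  if (length(sets) == 0L) stop("no structure sets supplied")
  if (is.null(inventory)) inventory <- organ_inventory()$organ
  versions <- unique(vapply(sets, `[[`, "", "version_label"))
  patients <- unique(vapply(sets, `[[`, "", "patient_id"))

  # canonicalise within each set, detecting ambiguous collisions
  canon_sets <- lapply(sets, function(ss) {
    raw <- names(ss$structures)
    canon <- vapply(raw, canonical_name, "", name_map = name_map)
    if (anyDuplicated(canon)) {
      dup <- unique(canon[duplicated(canon)])
      stop("ambiguous name map: raw names {",
           paste(raw[canon %in% dup], collapse = ", "),
           "} map to one canonical name within patient ", ss$patient_id,
           " version ", ss$version_label)
    }
    names(ss$structures) <- unname(canon)
    ss
  })

  unknown <- character()
  pairings <- list()
  for (pid in patients) {
    psets <- canon_sets[vapply(canon_sets, `[[`, "", "patient_id") == pid]
    pv <- vapply(psets, `[[`, "", "version_label")
    organs <- sort(unique(unlist(lapply(psets, function(s) names(s$structures)))))
    for (org in organs) {
      if (!(org %in% inventory)) unknown <- union(unknown, org)
      masks <- stats::setNames(vector("list", length(pv)), pv)
      for (i in seq_along(psets)) {
        m <- get_mask(psets[[i]], org)
        if (!is.null(m)) masks[[pv[i]]] <- m
      }
      missing_in <- pv[vapply(masks, is.null, TRUE)]
      pairings[[length(pairings) + 1L]] <- structure(
        list(patient_id = pid, organ_name = org, masks = masks,
             missing_in = missing_in),
        class = "organ_pairing")
    }
  }
  structure(pairings, versions = versions, unknown_organs = unknown)
}

#' Anchor-based cropping rule
#'
#' Declares that one organ's superior/inferior extent is to be limited to
#' a z window around another organ before metric computation. The shipped
#' default restricts the rectum to 1 cm above and below the prostate, the
#' standard pre-processing that removes delineation-extent variation at
#' the rectal ends.
#'
#' @param target_organ canonical name of the organ to crop.
#' @param anchor_organ canonical name of the anchoring organ.
#' @param superior_margin_mm,inferior_margin_mm margins in mm (>= 0).
#' @return An object of class `crop_rule`.
#' @export
crop_rule <- function(target_organ, anchor_organ,
                      superior_margin_mm = 10, inferior_margin_mm = 10) {
  if (superior_margin_mm < 0 || inferior_margin_mm < 0)
    stop("crop margins must be >= 0")
  structure(list(target_organ = tolower(target_organ),
                 anchor_organ = tolower(anchor_organ),
                 superior_margin_mm = superior_margin_mm,
                 inferior_margin_mm = inferior_margin_mm),
            class = "crop_rule")
}

#' Default crop rules
#'
#' @return List with the single prostate-anchored rectum crop (10 mm
#'   margins each way).
#' @export
default_crop_rules <- function() list(crop_rule("rectum", "prostate"))

anchor_z_window <- function(anchor, rule) {
  occ <- which(apply(anchor$voxels, 3, any))
  zp <- slice_planes(anchor$geometry)
  c(min(zp[occ]) - rule$inferior_margin_mm,
    max(zp[occ]) + rule$superior_margin_mm)
}

#' Crop a target mask to a z window around an anchor mask
#'
#' Zeroes every target voxel lying on a slice whose plane falls outside
#' `[anchor_zmin - inferior_margin, anchor_zmax + superior_margin]`, where
#' the anchor extent is the mm z range of its occupied slices. The window
#' bounds are inclusive, so a 10 mm margin on 2 mm slices keeps exactly
#' five slices beyond the anchor on each side. A target left empty by the
#' crop is returned as an empty mask (flagged downstream), not an error.
#'
#' @param target,anchor [binary_mask()] objects on one geometry; the
#'   anchor must be nonempty.
#' @param rule a [crop_rule()].
#' @return The cropped [binary_mask()].
#' @export
crop_to_anchor <- function(target, anchor, rule) {
  check_pair(target, anchor)
  if (mask_is_empty(anchor)) stop("anchor required for crop: anchor mask is empty")
  win <- anchor_z_window(anchor, rule)
  crop_to_window(target, win)
}

crop_to_window <- function(target, win) {
  zp <- slice_planes(target$geometry)
  keep <- zp >= win[1] - 1e-9 & zp <= win[2] + 1e-9
  v <- target$voxels
  v[, , !keep] <- FALSE
  binary_mask(v, target$geometry)
}

#' Apply crop rules across a paired cohort
#'
#' For each rule and patient the crop window is computed ONCE, from the
#' anchor mask of a single designated version (the ground-truth label if
#' present, else the first version label), and that same window is applied
#' to the target organ of every version. Version differences inside the
#' window are thereby preserved while superior/inferior delineation-extent
#' variation is excluded; anchoring each version on its own prostate would
#' confound the version comparison.
#'
#' @param pairings output of [match_structures()].
#' @param crop_rules list of [crop_rule()] objects.
#' @param anchor_version version label whose anchor defines the window;
#'   `NULL` selects `"ground_truth"` if present, else the first version.
#' @return The pairings with cropped target masks.
#' @export
apply_crop_rules <- function(pairings, crop_rules,
                             anchor_version = NULL) {
  if (length(crop_rules) == 0L) return(pairings)
  versions <- attr(pairings, "versions")
  if (is.null(anchor_version))
    anchor_version <- if ("ground_truth" %in% versions) "ground_truth"
      else versions[1]
  by_pat <- split(seq_along(pairings),
                  vapply(pairings, `[[`, "", "patient_id"))
  for (rule in crop_rules) {
    for (idx in by_pat) {
      orgs <- vapply(pairings[idx], `[[`, "", "organ_name")
      ti <- idx[orgs == rule$target_organ]
      ai <- idx[orgs == rule$anchor_organ]
      if (length(ti) == 0L) next
      if (length(ai) == 0L)
        stop("crop rule for '", rule$target_organ, "': anchor organ '",
             rule$anchor_organ, "' absent for patient ",
             pairings[[ti]]$patient_id)
      anchor <- pairings[[ai]]$masks[[anchor_version]]
      if (is.null(anchor) || mask_is_empty(anchor))
        stop("anchor required for crop: '", rule$anchor_organ,
             "' is missing or empty in version ", anchor_version,
             " for patient ", pairings[[ti]]$patient_id)
      win <- anchor_z_window(anchor, rule)
      for (v in names(pairings[[ti]]$masks)) {
        m <- pairings[[ti]]$masks[[v]]
        if (!is.null(m))
          pairings[[ti]]$masks[[v]] <- crop_to_window(m, win)
      }
    }
  }
  pairings
}

#' Metric table for one version pair
#'
#' Computes the (DSC, MDTA, HD) triple for every pairing between two
#' version labels. Pairings missing the organ in either version are
#' reported with status `"missing"`; empty-mask pairs propagate
#' `"undefined_empty"`.
#'
#' @param pairings output of [match_structures()] (optionally cropped via
#'   [apply_crop_rules()]).
#' @param version_a,version_b version labels to compare.
#' @return Data frame: `patient_id`, `organ`, `dsc`, `mdta_mm`, `hd_mm`,
#'   `status`.
#' @export
compute_pair_metrics <- function(pairings, version_a, version_b) {
  rows <- lapply(pairings, function(p) {
    a <- p$masks[[version_a]]; b <- p$masks[[version_b]]
    if (is.null(a) || is.null(b)) {
      status <- "missing"
      tr <- list(dsc = NA_real_, mdta_mm = NA_real_, hd_mm = NA_real_)
    } else {
      tr <- metric_triple(a, b)
      status <- tr$status
    }
    data.frame(patient_id = p$patient_id, organ = p$organ_name,
               dsc = tr$dsc, mdta_mm = tr$mdta_mm, hd_mm = tr$hd_mm,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
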