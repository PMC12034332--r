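resolve_cohorts <- function(sets_by_version) {
  out <- lapply(sets_by_version, function(x) {
    if (is.character(x)) read_cohort(x) else x
  })
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("`sets_by_version` must be named by version label")
  # force every set to carry its list's version label
  for (v in names(out))
    out[[v]] <- lapply(out[[v]], function(ss)
      structure_set(ss$patient_id, v, ss$structures, ss$geometry))
  out
}

report_header <- function(settings) {
  c(list(tool = "segqa",
         tool_version = as.character(utils::packageVersion("segqa")),
         units = "mm"),
    settings)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the screening stage
#'
#' The routine first stage of the method: for each adjacent pair of
#' version labels, pair structures across versions, apply the crop rules,
#' compute the per-patient (DSC, MDTA, HD) table, and screen it under the
#' requested criteria. Writes, per version pair: the per-contour metric
#' table, a per-organ summary per criteria set, flag lists, bar-figure
#' data (per-organ means with both criteria's threshold lines), and a JSON
#' report echoing every setting that affects the numbers.
#'
#' @param sets_by_version named list, version label -> list of
#'   [structure_set()]s or a cohort directory path. Order defines the
#'   version sequence; adjacent labels are compared.
#' @param criteria character vector of preset names (`"A"`, `"B"`) and/or
#'   [criteria_set()] objects.
#' @param name_map raw -> canonical organ name map.
#' @param crop_rules list of [crop_rule()]s; [default_crop_rules()] by
#'   default.
#' @param anchor_version version anchoring crops (see
#'   [apply_crop_rules()]).
#' @param aggregation organ-level flag mode, see [screen_cohort()].
#' @param out_dir output directory, created if needed; `NULL` writes
#'   nothing.
#' @return (Invisibly) list with per-pair results (`metrics`, one
#'   screening per criteria), `any_flagged`, and `exit_status` (0 clean,
#'   2 flags raised).
#' @export
run_screen <- function(sets_by_version, criteria = c("A", "B"),
                       name_map = NULL, crop_rules = default_crop_rules(),
                       anchor_version = NULL,
                       aggregation = "per_organ_mean", out_dir = NULL) {
  cohorts <- resolve_cohorts(sets_by_version)
  versions <- names(cohorts)
  if (length(versions) < 2L) stop("screening needs at least two version labels")
  crit_list <- lapply(criteria, function(cr)
    if (inherits(cr, "criteria_set")) cr else criteria_preset(cr))
  names(crit_list) <- vapply(crit_list, `[[`, "", "name")

  all_sets <- unlist(unname(cohorts), recursive = FALSE)
  pairings <- match_structures(all_sets, name_map = name_map)
  pairings <- apply_crop_rules(pairings, crop_rules, anchor_version)
  if (length(pairings) == 0L) stop("zero matched organs across versions")

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  results <- list()
  any_flagged <- FALSE
  for (i in seq_len(length(versions) - 1L)) {
    va <- versions[i]; vb <- versions[i + 1L]
    tag <- paste0(va, "_vs_", vb)
    metrics <- compute_pair_metrics(pairings, va, vb)
    screens <- lapply(crit_list, function(cr)
      screen_cohort(metrics, cr, aggregation = aggregation))
    flagged <- lapply(screens, function(s) s$summary$organ[s$summary$flagged])
    any_flagged <- any_flagged || any(lengths(flagged) > 0L)

    if (!is.null(out_dir)) {
      utils::write.csv(metrics,
                       file.path(out_dir, paste0("metrics_", tag, ".csv")),
                       row.names = FALSE)
      fig <- do.call(rbind, lapply(names(screens), function(nm) {
        s <- screens[[nm]]$summary
        data.frame(criteria = nm, organ = s$organ,
                   mean_dsc = s$mean_dsc, mean_mdta_mm = s$mean_mdta_mm,
                   mean_hd_mm = s$mean_hd_mm,
                   dsc_min = screens[[nm]]$criteria$dsc_min,
                   mdta_max_mm = screens[[nm]]$criteria$mdta_max_mm,
                   hd_max_mm = screens[[nm]]$criteria$hd_max_mm,
                   flagged = s$flagged, stringsAsFactors = FALSE)
      }))
      utils::write.csv(fig,
                       file.path(out_dir, paste0("figure_data_", tag, ".csv")),
                       row.names = FALSE)
      for (nm in names(screens)) {
        utils::write.csv(screens[[nm]]$summary,
                         file.path(out_dir, paste0("organ_summary_", tag,
                                                   "_criteria_", nm, ".csv")),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(organ = flagged[[nm]], stringsAsFactors = FALSE),
          file.path(out_dir, paste0("flags_", tag, "_criteria_", nm, ".csv")),
          row.names = FALSE)
      }
    }
    results[[tag]] <- list(metrics = metrics, screens = screens,
                           flagged = flagged)
  }

  if (!is.null(out_dir)) {
    rep <- list(
      header = report_header(list(
        stage = "screen", versions = versions,
        criteria = lapply(crit_list, unclass),
        aggregation = aggregation,
        anchor_version = if (is.null(anchor_version)) "auto" else anchor_version,
        crop_rules = lapply(crop_rules, unclass),
        unknown_organs = attr(pairings, "unknown_organs"))),
      flags = lapply(results, `[[`, "flagged"),
      summaries = lapply(results, function(r)
        lapply(r$screens, function(s) s$summary)))
    write_json_report(rep, file.path(out_dir, "screen_report.json"))
  }
  invisible(list(results = results, pairings = pairings,
                 any_flagged = any_flagged,
                 exit_status = if (any_flagged) 2L else 0L))
}

#' Run the ground-truth evaluation stage
#'
#' The second stage: re-evaluates selected organs of each software version
#' against the expert ground-truth contours and tests each geometric index
#' for per-organ differences between versions with the paired Wilcoxon
#' signed-rank test. Writes the raw ground-truth metric table, the
#' statistics table, a publication-style summary table (mean (min–max)
#' cells with significance marks), and a JSON report.
#'
#' @param sets_by_version named list including the ground-truth label.
#' @param versions non-ground-truth version labels to evaluate, in order;
#'   adjacent labels are tested pairwise. Default: all non-GT labels.
#' @param gt_label ground-truth version label.
#' @param organs `"all"`, or a character vector (e.g. the screening flag
#'   list). An empty vector is a warning no-op, not an error.
#' @param alpha significance level.
#' @param zero_policy zero-difference policy, see
#'   [wilcoxon_signed_rank()].
#' @param name_map,crop_rules,anchor_version as in [run_screen()].
#' @param out_dir output directory; `NULL` writes nothing.
#' @return (Invisibly) list: `gt_metrics`, `stats` (one per version
#'   pair), `summary_table`, `exit_status` (0 ok, 3 no-op).
#' @export
run_evaluate <- function(sets_by_version, versions = NULL,
                         gt_label = "ground_truth", organs = "all",
                         alpha = 0.05, zero_policy = "drop",
                         name_map = NULL, crop_rules = default_crop_rules(),
                         anchor_version = NULL, out_dir = NULL) {
  cohorts <- resolve_cohorts(sets_by_version)
  if (!(gt_label %in% names(cohorts)))
    stop("ground-truth label '", gt_label, "' not supplied")
  if (is.null(versions)) versions <- setdiff(names(cohorts), gt_label)
  organ_filter <- if (identical(organs, "all")) NULL else unique(tolower(organs))
  if (!is.null(organ_filter) && length(organ_filter) == 0L) {
    warning("empty organ list: evaluation is a no-op")
    return(invisible(list(gt_metrics = NULL, stats = NULL,
                          summary_table = NULL, exit_status = 3L)))
  }

  all_sets <- unlist(unname(cohorts), recursive = FALSE)
  pairings <- match_structures(all_sets, name_map = name_map)
  pairings <- apply_crop_rules(pairings, crop_rules, anchor_version)
  gt_metrics <- ground_truth_metrics(pairings, gt_label = gt_label,
                                     versions = versions,
                                     organs = organ_filter)
  stats_list <- list()
  if (length(versions) >= 2L) {
    for (i in seq_len(length(versions) - 1L)) {
      va <- versions[i]; vb <- versions[i + 1L]
      stats_list[[paste0(va, "_vs_", vb)]] <-
        version_stat_table(gt_metrics, va, vb, alpha = alpha,
                           zero_policy = zero_policy)
    }
  }
  summary_table <- if (length(stats_list))
    build_summary_table(unname(stats_list)) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(gt_metrics, file.path(out_dir, "gt_metrics.csv"),
                     row.names = FALSE)
    if (length(stats_list)) {
      utils::write.csv(do.call(rbind, unname(stats_list)),
                       file.path(out_dir, "stats.csv"), row.names = FALSE)
      utils::write.csv(summary_table,
                       file.path(out_dir, "summary_table.csv"),
                       row.names = FALSE)
    }
    rep <- list(
      header = report_header(list(
        stage = "evaluate", gt_label = gt_label, versions = versions,
        organs = if (is.null(organ_filter)) "all" else organ_filter,
        alpha = alpha, zero_policy = zero_policy,
        crop_rules = lapply(crop_rules, unclass),
        excluded = attr(gt_metrics, "excluded"))),
      stats = stats_list)
    write_json_report(rep, file.path(out_dir, "evaluate_report.json"))
  }
  invisible(list(gt_metrics = gt_metrics, stats = stats_list,
                 summary_table = summary_table, exit_status = 0L))
}

boundary_2d <- function(m) {
  d <- dim(m)
  inner <- m
  pad <- function(v, dr, dc) {
    out <- matrix(FALSE, d[1], d[2])
    r <- seq_len(d[1]) + dr; c <- seq_len(d[2]) + dc
    ok_r <- r >= 1 & r <= d[1]; ok_c <- c >= 1 & c <= d[2]
    out[ok_r, ok_c] <- v[r[ok_r], c[ok_c]]
    out
  }
  nb <- pad(m, 1, 0) & pad(m, -1, 0) & pad(m, 0, 1) & pad(m, 0, -1)
  m & !nb
}

overlay_colors <- function(labels) {
  pal <- c(old = "red", new = "yellow", ground_truth = "green")
  extra <- c("cyan", "magenta", "orange", "blue")
  cols <- character(length(labels)); names(cols) <- labels
  for (i in seq_along(labels)) {
    cols[i] <- if (labels[i] %in% names(pal)) pal[[labels[i]]]
      else extra[(i - 1L) %% length(extra) + 1L]
  }
  cols
}

#' Write section overlays of one organ across versions
#'
#' Renders transverse, sagittal and coronal sections through the organ
#' centroid (nearest grid plane; the centroid of the first version where
#' the organ is nonempty), with each version's in-plane mask boundary in a
#' distinct colour, as PNG images plus a JSON legend. Versions where the
#' structure is empty are marked `"(empty)"` in the legend.
#'
#' @param sets_by_version named list of cohorts (or directories).
#' @param patient patient id.
#' @param organ organ name (canonical).
#' @param out_dir output directory.
#' @param name_map optional raw -> canonical organ name map.
#' @return (Invisibly) character vector of files written.
#' @export
run_overlay <- function(sets_by_version, patient, organ, out_dir,
                        name_map = NULL) {
  cohorts <- resolve_cohorts(sets_by_version)
  organ <- tolower(organ)
  masks <- list()
  geom <- NULL
  for (v in names(cohorts)) {
    ss <- Filter(function(s) s$patient_id == patient, cohorts[[v]])
    if (length(ss) == 0L) next
    ss <- ss[[1]]
    nm <- names(ss$structures)
    canon <- vapply(nm, canonical_name, "", name_map = name_map)
    hit <- which(canon == organ)
    if (length(hit) == 1L) {
      masks[[v]] <- get_mask(ss, nm[hit])
      geom <- ss$geometry
    }
  }
  if (length(masks) == 0L)
    stop("organ '", organ, "' absent from every version for patient ", patient)
  nonempty <- Filter(Negate(mask_is_empty), masks)
  if (length(nonempty) == 0L)
    stop("organ '", organ, "' is empty in every version for patient ", patient)
  ctr <- mask_centroid_mm(nonempty[[1]])
  planes <- vapply(1:3, function(ax)
    which.min(abs(axis_centers(geom, ax) - ctr[ax])), integer(1))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cols <- overlay_colors(names(masks))
  rgb_of <- function(col) grDevices::col2rgb(col)[, 1] / 255
  sections <- list(
    transverse = function(v) v[, , planes[3]],
    sagittal = function(v) v[planes[1], , ],
    coronal = function(v) v[, planes[2], ])
  files <- character()
  for (sec in names(sections)) {
    base <- NULL
    for (v in names(masks)) {
      sl <- sections[[sec]](masks[[v]]$voxels)
      if (is.null(base)) base <- array(0, c(nrow(sl), ncol(sl), 3))
      if (any(sl)) {
        b <- boundary_2d(sl)
        rgb <- rgb_of(cols[[v]])
        for (ch in 1:3) {
          plane <- base[, , ch]
          plane[b] <- rgb[ch]
          base[, , ch] <- plane
        }
      }
    }
    f <- file.path(out_dir, sprintf("%s_%s_%s.png", patient, organ, sec))
    png::writePNG(aperm(base, c(2, 1, 3)), f)
    files <- c(files, f)
  }
  legend <- lapply(names(masks), function(v)
    list(version = v, color = unname(cols[[v]]),
         empty = mask_is_empty(masks[[v]]),
         label = if (mask_is_empty(masks[[v]])) paste0(v, " (empty)") else v))
  lf <- file.path(out_dir, sprintf("%s_%s_legend.json", patient, organ))
  write_json_report(legend, lf)
  invisible(c(files, lf))
}

#' Read a run configuration file
#'
#' YAML configuration for the command-line interface. Criteria thresholds
#' are written in cm in the file (the unit screening criteria are usually
#' quoted in) and converted to mm once here; everything downstream is mm.
#'
#' Recognised keys: `versions` (label -> cohort directory, in comparison
#' order), `gt_label`, `name_map`, `crop_rules` (list of target / anchor /
#' superior_margin_mm / inferior_margin_mm), `criteria` (preset names or
#' custom blocks with `name`, `dsc_min`, `mdta_max_cm`, `hd_max_cm`),
#' `alpha`, `zero_policy`, `aggregation`, `out`, `seed`.
#'
#' @param path YAML file.
#' @return List of parsed settings; criteria as [criteria_set()] objects,
#'   crop rules as [crop_rule()] objects.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$criteria)) {
    cfg$criteria <- lapply(cfg$criteria, function(cr) {
      if (is.character(cr)) criteria_preset(cr)
      else criteria_set(cr$name, cr$dsc_min,
                        mdta_max_mm = cr$mdta_max_cm * 10,
                        hd_max_mm = cr$hd_max_cm * 10)
    })
  }
  if (!is.null(cfg$crop_rules)) {
    cfg$crop_rules <- lapply(cfg$crop_rules, function(r)
      crop_rule(r$target, r$anchor,
                superior_margin_mm = if (is.null(r$superior_margin_mm)) 10
                  else r$superior_margin_mm,
                inferior_margin_mm = if (is.null(r$inferior_margin_mm)) 10
                  else r$inferior_margin_mm))
  }
  if (!is.null(cfg$name_map)) cfg$name_map <- unlist(cfg$name_map)
  cfg
}
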