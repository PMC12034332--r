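#' Screening criteria set
#'
#' The three thresholds that decide whether a version pair's metric triple
#' marks an organ as notably modified. Two presets ship with the package
#' (see [criteria_preset()]):
#'
#' * criteria A (strict identification): DSC 0.99, MDTA 0.05 cm, HD 0.2 cm
#'   — tuned to catch any deliberate change, since 0.2 cm is a single CT
#'   slice;
#' * criteria B (standard near-identity): DSC 0.9, MDTA 0.2 cm, HD 1.0 cm
#'   — the conventional thresholds for treating two contours as nearly
#'   identical.
#'
#' All thresholds are stored in mm internally; user-facing configuration
#' may use cm (see [read_run_config()]), converted once at parse time.
#'
#' @param name label (`"A"`, `"B"`, or custom).
#' @param dsc_min minimum acceptable DSC, in (0, 1].
#' @param mdta_max_mm maximum acceptable MDTA in mm (>= 0).
#' @param hd_max_mm maximum acceptable HD in mm (>= `mdta_max_mm`).
#' @return An object of class `criteria_set`.
#' @export
criteria_set <- function(name, dsc_min, mdta_max_mm, hd_max_mm) {
  if (!(dsc_min > 0 && dsc_min <= 1)) stop("dsc_min must be in (0, 1]")
  if (mdta_max_mm < 0) stop("mdta_max_mm must be >= 0")
  if (hd_max_mm < mdta_max_mm) stop("hd_max_mm must be >= mdta_max_mm")
  structure(list(name = as.character(name), dsc_min = dsc_min,
                 mdta_max_mm = mdta_max_mm, hd_max_mm = hd_max_mm),
            class = "criteria_set")
}

#' Shipped criteria presets
#'
#' @param name `"A"` (strict: DSC 0.99, MDTA 0.5 mm, HD 2 mm) or `"B"`
#'   (standard: DSC 0.9, MDTA 2 mm, HD 10 mm).
#' @return A [criteria_set()].
#' @export
criteria_preset <- function(name = c("A", "B")) {
  name <- match.arg(name)
  switch(name,
         A = criteria_set("A", dsc_min = 0.99, mdta_max_mm = 0.5, hd_max_mm = 2),
         B = criteria_set("B", dsc_min = 0.90, mdta_max_mm = 2,   hd_max_mm = 10))
}

#' Evaluate one metric triple against a criteria set
#'
#' An index violates only on the wrong side of its threshold under strict
#' inequality: DSC violates iff `dsc < dsc_min`, MDTA iff
#' `mdta_mm > mdta_max_mm`, HD iff `hd_mm > hd_max_mm`. A value exactly AT
#' a threshold does not violate — the criteria are written as target
#' values, not open intervals. The organ is flagged iff any single index
#' violates; a triple with status `undefined_empty` (an organ empty or
#' vanished in one version) always flags, with all three indices marked.
#'
#' @param triple a [metric_triple()].
#' @param criteria a [criteria_set()].
#' @param patient_id,organ_name optional identifiers carried into the
#'   verdict.
#' @return An object of class `screening_verdict`: fields `flagged`,
#'   `violated` (subset of `c("dsc", "mdta", "hd")`), `criteria`, `triple`.
#' @export
evaluate_criteria <- function(triple, criteria,
                              patient_id = NA_character_,
                              organ_name = NA_character_) {
  if (!inherits(criteria, "criteria_set")) stop("`criteria` must be a criteria_set")
  if (!inherits(triple, "metric_triple")) stop("`triple` must be a metric_triple")
  if (triple$status == "undefined_empty") {
    violated <- c("dsc", "mdta", "hd")
  } else {
    violated <- c("dsc", "mdta", "hd")[c(
      triple$dsc < criteria$dsc_min,
      triple$mdta_mm > criteria$mdta_max_mm,
      triple$hd_mm > criteria$hd_max_mm)]
  }
  structure(list(patient_id = patient_id, organ_name = organ_name,
                 criteria = criteria$name, flagged = length(violated) > 0L,
                 violated = violated, triple = triple),
            class = "screening_verdict")
}

triple_from_row <- function(row) {
  structure(list(dsc = row$dsc, mdta_mm = row$mdta_mm, hd_mm = row$hd_mm,
                 status = row$status),
            class = "metric_triple")
}

#' Screen a cohort metric table against a criteria set
#'
#' Applies [evaluate_criteria()] to every per-patient metric row of a
#' version pair and aggregates to an organ-level flag. Under
#' `"per_organ_mean"` (default, matching the per-organ bar-summary
#' reading) an organ is flagged iff the mean triple across its computed
#' patients violates, or any patient pair was `undefined_empty`. Under
#' `"per_patient"` an organ is flagged iff any single patient violates —
#' kept because a worst case (an isolated far-away region in one patient)
#' can be invisible in means. Rows with status `"missing"` (organ absent
#' from a version) are excluded from metrics but counted in the summary.
#'
#' @param metrics data frame from [compute_pair_metrics()].
#' @param criteria a [criteria_set()].
#' @param aggregation `"per_organ_mean"` or `"per_patient"`.
#' @return List with `verdicts` (per-patient data frame: flagged,
#'   violated) and `summary` (per-organ data frame: n, mean metrics,
#'   n_undefined, n_missing, flagged, violated), plus `criteria` and
#'   `aggregation`.
#' @export
screen_cohort <- function(metrics, criteria,
                          aggregation = c("per_organ_mean", "per_patient")) {
  aggregation <- match.arg(aggregation)
  if (nrow(metrics) == 0L) stop("empty cohort: no metric rows to screen")

  verdict_rows <- lapply(seq_len(nrow(metrics)), function(i) {
    row <- metrics[i, ]
    if (row$status == "missing")
      return(data.frame(patient_id = row$patient_id, organ = row$organ,
                        flagged = TRUE, violated = "missing",
                        status = row$status, stringsAsFactors = FALSE))
    v <- evaluate_criteria(triple_from_row(row), criteria,
                           row$patient_id, row$organ)
    data.frame(patient_id = row$patient_id, organ = row$organ,
               flagged = v$flagged,
               violated = paste(v$violated, collapse = ","),
               status = row$status, stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, verdict_rows)

  summary_rows <- lapply(split(seq_len(nrow(metrics)), metrics$organ), function(idx) {
    sub <- metrics[idx, ]
    comp <- sub[sub$status == "computed", , drop = FALSE]
    n_undef <- sum(sub$status == "undefined_empty")
    n_missing <- sum(sub$status == "missing")
    mean_triple <- structure(
      list(dsc = if (nrow(comp)) mean(comp$dsc) else NA_real_,
           mdta_mm = if (nrow(comp)) mean(comp$mdta_mm) else NA_real_,
           hd_mm = if (nrow(comp)) mean(comp$hd_mm) else NA_real_,
           status = if (nrow(comp)) "computed" else "undefined_empty"),
      class = "metric_triple")
    if (aggregation == "per_organ_mean") {
      v <- evaluate_criteria(mean_triple, criteria, organ_name = sub$organ[1])
      flagged <- v$flagged || n_undef > 0L
      violated <- paste(v$violated, collapse = ",")
    } else {
      sub_flag <- verdicts$flagged[idx] & verdicts$status[idx] != "missing"
      flagged <- any(sub_flag) || n_undef > 0L
      violated <- paste(sort(unique(unlist(
        strsplit(verdicts$violated[idx][sub_flag], ",")))), collapse = ",")
    }
    data.frame(organ = sub$organ[1], n = nrow(comp),
               mean_dsc = mean_triple$dsc, mean_mdta_mm = mean_triple$mdta_mm,
               mean_hd_mm = mean_triple$hd_mm, n_undefined = n_undef,
               n_missing = n_missing, flagged = flagged, violated = violated,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  list(verdicts = verdicts, summary = summary,
       criteria = criteria, aggregation = aggregation)
}
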