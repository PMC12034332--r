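#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences `a - b`, the test used
#' to decide whether a geometric index differs between software versions
#' across patients. Two zero-difference policies are exposed because
#' version-identical contours produce many exact zeros:
#'
#' * `"drop"` (default, the classic test): zero differences are discarded
#'   before ranking. The null distribution is exact (via the signed-rank
#'   distribution) when the effective n is <= 25 and there are no tied
#'   ranks, and a normal approximation with tie and continuity correction
#'   otherwise.
#' * `"keep"` (zero-inclusive): absolute differences are ranked with zeros
#'   included, zeros then contribute nothing to the statistic. The null is
#'   enumerated exactly over all sign assignments when the number of
#'   nonzero differences is <= 16, with a zero- and tie-corrected normal
#'   approximation otherwise.
#'
#' If every difference is zero the test returns p = 1 (no evidence of
#' change). If `zero_policy = "drop"` leaves no differences, the result is
#' marked not testable rather than fabricating a p-value.
#'
#' @param a,b paired numeric vectors of equal length (>= 1).
#' @param alpha significance level (default 0.05).
#' @param zero_policy `"drop"` or `"keep"`.
#' @return An object of class `wilcoxon_result`: `statistic` (V, the sum
#'   of positive-difference ranks), `n`, `n_effective`, `p_value`,
#'   `significant`, `testable`, `method`, `zero_policy`, `alpha`.
#' @export
wilcoxon_signed_rank <- function(a, b, alpha = 0.05,
                                 zero_policy = c("drop", "keep")) {
  zero_policy <- match.arg(zero_policy)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 1L) stop("at least one pair is required")
  if (anyNA(a) || anyNA(b)) stop("paired values must not contain NA")
  d <- a - b
  n <- length(d)

  res <- function(V, ne, p, method, testable = TRUE) {
    structure(list(statistic = V, n = n, n_effective = ne,
                   p_value = p, significant = testable && !is.na(p) && p < alpha,
                   testable = testable, method = method,
                   zero_policy = zero_policy, alpha = alpha),
              class = "wilcoxon_result")
  }

  if (all(d == 0)) return(res(0, 0L, 1, "all_zero"))

  if (zero_policy == "drop") {
    dd <- d[d != 0]
    ne <- length(dd)
    if (ne == 0L) return(res(NA_real_, 0L, NA_real_, "not_testable", FALSE))
    r <- rank(abs(dd))
    V <- sum(r[dd > 0])
    if (ne <= 25L && !anyDuplicated(r)) {
      p <- min(1, 2 * min(stats::psignrank(V, ne),
                          1 - stats::psignrank(V - 1, ne)))
      return(res(V, ne, p, "exact"))
    }
    # normal approximation with tie correction and continuity correction
    mu <- ne * (ne + 1) / 4
    tie <- table(r)
    sigma2 <- ne * (ne + 1) * (2 * ne + 1) / 24 -
      sum(tie^3 - tie) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    return(res(V, ne, min(1, 2 * stats::pnorm(-abs(z))), "normal_approx"))
  }

  # keep: zero-inclusive ranks, zeros contribute nothing to V
  r <- rank(abs(d))
  nz <- which(d != 0)
  V <- sum(r[d > 0])
  m <- length(nz)
  if (m <= 16L) {
    # exact enumeration of the null over sign assignments of nonzero pairs
    rv <- r[nz]
    vals <- 0
    for (ri in rv) vals <- c(vals, vals + ri)  # distribution as multiset sums
    p <- min(1, 2 * min(mean(vals <= V + 1e-12), mean(vals >= V - 1e-12)))
    return(res(V, m, p, "exact_enumeration"))
  }
  z0 <- n - m
  mu <- (n * (n + 1) - z0 * (z0 + 1)) / 4
  tie <- table(r[nz])
  sigma2 <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
    sum(tie^3 - tie) / 48
  z <- V - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  res(V, m, min(1, 2 * stats::pnorm(-abs(z))), "normal_approx")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> V = %s, n_eff = %d, p = %s (%s, zeros: %s)\n",
              format(x$statistic), x$n_effective, format(x$p_value),
              x$method, x$zero_policy))
  invisible(x)
}

#' Metric triples of each version against expert ground truth
#'
#' Re-evaluates organs against the expert (ground-truth) delineation: for
#' every patient and organ, the (DSC, MDTA, HD) triple of each non-GT
#' version's mask versus the ground-truth mask. In pipeline use the organ
#' list is restricted to the screening flags; standalone use evaluates all
#' organs. Organs missing from the ground truth are excluded with an entry
#' in the `excluded` attribute, never silently.
#'
#' @param pairings output of [match_structures()] (optionally cropped).
#' @param gt_label the ground-truth version label.
#' @param versions version labels to evaluate; default all non-GT labels.
#' @param organs optional character vector restricting the organs.
#' @return Data frame: `patient_id`, `organ`, `version`, `dsc`, `mdta_mm`,
#'   `hd_mm`, `status`; attribute `excluded` lists organ/patient
#'   combinations without ground truth.
#' @export
ground_truth_metrics <- function(pairings, gt_label = "ground_truth",
                                 versions = NULL, organs = NULL) {
  all_versions <- attr(pairings, "versions")
  if (!is.null(all_versions) && !(gt_label %in% all_versions))
    stop("ground-truth label '", gt_label, "' absent from the cohort")
  if (is.null(versions)) versions <- setdiff(all_versions, gt_label)
  rows <- list(); excluded <- list()
  seen_gt <- FALSE
  for (p in pairings) {
    if (!is.null(organs) && !(p$organ_name %in% organs)) next
    gt <- p$masks[[gt_label]]
    if (is.null(gt)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(patient_id = p$patient_id, organ = p$organ_name,
                   reason = "no ground truth", stringsAsFactors = FALSE)
      next
    }
    seen_gt <- TRUE
    for (v in versions) {
      m <- p$masks[[v]]
      if (is.null(m)) {
        st <- "missing"
        tr <- list(dsc = NA_real_, mdta_mm = NA_real_, hd_mm = NA_real_)
      } else {
        tr <- metric_triple(m, gt)
        st <- tr$status
      }
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = p$patient_id, organ = p$organ_name,
                   version = v, dsc = tr$dsc, mdta_mm = tr$mdta_mm,
                   hd_mm = tr$hd_mm, status = st, stringsAsFactors = FALSE)
    }
  }
  if (!seen_gt && length(rows) == 0L)
    stop("ground-truth label '", gt_label, "' absent for every selected organ")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
    else NULL
  out
}

metric_columns <- c(dsc = "dsc", mdta = "mdta_mm", hd = "hd_mm")

#' Per-organ paired statistics between two versions
#'
#' For each organ and each geometric index, pairs the patients with
#' computed ground-truth triples in BOTH versions and runs the paired
#' Wilcoxon signed-rank test, reporting means and ranges over exactly
#' those paired patients.
#'
#' @param gt_metrics data frame from [ground_truth_metrics()].
#' @param version_a,version_b the two version labels to compare.
#' @param alpha significance level.
#' @param zero_policy passed to [wilcoxon_signed_rank()].
#' @param p_adjust `"none"` (default, raw p-values) or `"holm"` applied
#'   across all organ x metric tests of this call.
#' @return Data frame: `organ`, `metric`, `version_a`, `version_b`, `n`,
#'   `mean_a`, `min_a`, `max_a`, `mean_b`, `min_b`, `max_b`, `p_value`,
#'   `significant`, `method`.
#' @export
version_stat_table <- function(gt_metrics, version_a, version_b,
                               alpha = 0.05, zero_policy = "drop",
                               p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  rows <- list()
  for (org in sort(unique(gt_metrics$organ))) {
    sub <- gt_metrics[gt_metrics$organ == org, ]
    a <- sub[sub$version == version_a & sub$status == "computed", ]
    b <- sub[sub$version == version_b & sub$status == "computed", ]
    common <- intersect(a$patient_id, b$patient_id)
    for (mn in names(metric_columns)) {
      col <- metric_columns[[mn]]
      if (length(common) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          organ = org, metric = mn, version_a = version_a,
          version_b = version_b, n = 0L,
          mean_a = NA_real_, min_a = NA_real_, max_a = NA_real_,
          mean_b = NA_real_, min_b = NA_real_, max_b = NA_real_,
          p_value = NA_real_, significant = FALSE, method = "not_testable",
          stringsAsFactors = FALSE)
        next
      }
      va <- a[[col]][match(common, a$patient_id)]
      vb <- b[[col]][match(common, b$patient_id)]
      w <- wilcoxon_signed_rank(va, vb, alpha = alpha,
                                zero_policy = zero_policy)
      rows[[length(rows) + 1L]] <- data.frame(
        organ = org, metric = mn, version_a = version_a,
        version_b = version_b, n = length(common),
        mean_a = mean(va), min_a = min(va), max_a = max(va),
        mean_b = mean(vb), min_b = min(vb), max_b = max(vb),
        p_value = w$p_value, significant = w$significant, method = w$method,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust == "holm") {
    idx <- !is.na(out$p_value)
    out$p_value[idx] <- stats::p.adjust(out$p_value[idx], method = "holm")
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  out
}

fmt_mean_range <- function(mean, min, max, digits = 2) {
  if (is.na(mean)) return("–")
  sprintf(paste0("%.", digits, "f (%.", digits, "f–%.", digits, "f)"),
          mean, min, max)
}

fmt_p <- function(p, significant) {
  if (is.na(p)) return("–")
  s <- if (p < 1e-3) sprintf("%.2e", p) else sprintf("%.3f", p)
  if (isTRUE(significant)) paste0(s, " *") else s
}

#' Publication-style per-organ summary table
#'
#' One row per organ; for each geometric index and version a
#' `"mean (min–max)"` cell over the paired patients, and a p-value column
#' per version pair per index (significant results marked `*`). Missing
#' organ/version combinations render as an en dash.
#'
#' @param stats one data frame from [version_stat_table()], or a list of
#'   them (several version pairs).
#' @param digits digits for the mean/range cells.
#' @return Data frame of formatted character cells, one organ per row.
#' @export
build_summary_table <- function(stats, digits = 2) {
  if (is.data.frame(stats)) stats <- list(stats)
  all <- do.call(rbind, stats)
  if (is.null(all) || nrow(all) == 0L) stop("no statistics to tabulate")
  versions <- unique(c(rbind(all$version_a, all$version_b)))
  organs <- unique(all$organ)
  out <- data.frame(organ = organs, stringsAsFactors = FALSE)
  for (mn in names(metric_columns)) {
    for (v in versions) {
      cells <- vapply(organs, function(org) {
        ra <- all[all$organ == org & all$metric == mn & all$version_a == v, ]
        if (nrow(ra) && ra$n[1] > 0L)
          return(fmt_mean_range(ra$mean_a[1], ra$min_a[1], ra$max_a[1], digits))
        rb <- all[all$organ == org & all$metric == mn & all$version_b == v, ]
        if (nrow(rb) && rb$n[1] > 0L)
          return(fmt_mean_range(rb$mean_b[1], rb$min_b[1], rb$max_b[1], digits))
        "–"
      }, character(1))
      out[[paste0(mn, "_", v)]] <- unname(cells)
    }
    for (s in stats) {
      va <- s$version_a[1]; vb <- s$version_b[1]
      cells <- vapply(organs, function(org) {
        r <- s[s$organ == org & s$metric == mn, ]
        if (nrow(r)) fmt_p(r$p_value[1], r$significant[1]) else "–"
      }, character(1))
      out[[paste0(mn, "_p_", va, "_vs_", vb)]] <- unname(cells)
    }
  }
  out
}
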