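test_that("the all-negative n = 6 case gives the exact two-sided p of 2/64", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12))
  expect_equal(w$p_value, 0.03125)
  expect_equal(w$method, "exact")
  expect_true(w$significant)
  expect_equal(w$statistic, 0)
})

test_that("exact p-values match the full 2^n sign-enumeration oracle", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    # distinct magnitudes -> no tied ranks -> exact path
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(seq(0.5, 20, by = 0.5), n)
    w <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(w$method, "exact")
    expect_equal(w$p_value, signrank_enum_oracle(d))
  }
})

test_that("exact mode agrees with the base wilcox.test cross-check", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    w <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(w$p_value, unname(ref$p.value))
    expect_equal(w$statistic, unname(ref$statistic))
  }
})

test_that("tied ranks fall back to the tie-corrected normal approximation", {
  a <- c(5, 4, 7, 9, 9, 7, 4, 5, 3, 3, 8, 8)
  b <- rep(6, 12)
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(w$p_value, unname(ref$p.value))
})

test_that("zero differences: p = 1 when all zero; drop-policy p unaffected by zero pairs", {
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$p_value, 1)
  expect_false(w$significant)
  a <- c(1.3, 4.1, 2.2, 8.5, 3.3, 6.1)
  b <- c(2.0, 3.0, 4.0, 5.0, 7.0, 1.0)
  base_p <- wilcoxon_signed_rank(a, b)$p_value
  with_zero <- wilcoxon_signed_rank(c(a, 5), c(b, 5))$p_value
  expect_equal(with_zero, base_p)
  # the keep policy ranks zeros, so its p may legitimately differ
  wk <- wilcoxon_signed_rank(c(a, 5), c(b, 5), zero_policy = "keep")
  expect_equal(wk$zero_policy, "keep")
  expect_true(wk$p_value >= 0 && wk$p_value <= 1)
})

test_that("keep policy enumerates the zero-inclusive null exactly for small n", {
  # zeros occupy low ranks; nonzero signs enumerate 2^m
  a <- c(3, 3, 10, -4, 7, -6)
  b <- c(3, 3, 2, 2, 1, 1)
  w <- wilcoxon_signed_rank(a, b, zero_policy = "keep")
  expect_equal(w$method, "exact_enumeration")
  d <- a - b
  r <- rank(abs(d))
  rv <- r[d != 0]
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(rv))))
  vals <- as.vector(signs %*% rv)
  p_oracle <- min(1, 2 * min(mean(vals <= v_obs), mean(vals >= v_obs)))
  expect_equal(w$p_value, p_oracle)
})

test_that("the p-value is invariant under positive affine rescaling of both members", {
  # signed-rank p depends on the rank order of |a - b|: positive affine
  # maps preserve it; nonlinear monotone maps in general do not
  set.seed(31)
  a <- rlnorm(10); b <- rlnorm(10)
  p0 <- wilcoxon_signed_rank(a, b)$p_value
  for (f in list(function(x) 5 * x + 2, function(x) 0.1 * x - 7)) {
    expect_equal(wilcoxon_signed_rank(f(a), f(b))$p_value, p0)
  }
})

test_that("one-signed differences pin the statistic, so any monotone map keeps their p", {
  set.seed(32)
  b <- rlnorm(8); a <- b + rlnorm(8)^2  # every difference positive
  p0 <- wilcoxon_signed_rank(a, b)$p_value
  for (f in list(log, sqrt, function(x) x^3)) {
    expect_equal(wilcoxon_signed_rank(f(a), f(b))$p_value, p0)
  }
})

gt_fixture <- function() {
  # two organs, two versions vs ground truth, 6 patients
  set.seed(77)
  pats <- sprintf("P%d", 1:6)
  rows <- expand.grid(patient_id = pats, organ = c("brain", "rectum"),
                      version = c("old", "new"), stringsAsFactors = FALSE)
  rows$dsc <- round(runif(nrow(rows), 0.8, 1), 3)
  rows$mdta_mm <- round(runif(nrow(rows), 0, 2), 3)
  rows$hd_mm <- rows$mdta_mm + round(runif(nrow(rows), 0, 8), 3)
  rows$status <- "computed"
  rows
}

test_that("version statistics pair only patients computed in both versions", {
  gm <- gt_fixture()
  gm$status[gm$patient_id == "P3" & gm$version == "new"] <- "undefined_empty"
  st <- version_stat_table(gm, "old", "new")
  expect_equal(unique(st$n), 5L)  # P3 excluded everywhere
  row <- st[st$organ == "brain" & st$metric == "dsc", ]
  sub <- gm[gm$organ == "brain" & gm$patient_id != "P3", ]
  expect_equal(row$mean_a, mean(sub$dsc[sub$version == "old"]))
  expect_equal(row$min_b, min(sub$dsc[sub$version == "new"]))
})

test_that("the summary table lays out mean (range) cells and dashes for missing data", {
  gm <- gt_fixture()
  st <- version_stat_table(gm, "old", "new")
  tab <- build_summary_table(st)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$organ, c("brain", "rectum"))
  expect_setequal(setdiff(names(tab), "organ"),
                  c(t(outer(c("dsc", "mdta", "hd"),
                            c("_old", "_new", "_p_old_vs_new"), paste0))))
  # cells recompute from the raw metric table
  sub <- gm[gm$organ == "brain" & gm$version == "old", ]
  expect_equal(tab$dsc_old[1],
               sprintf("%.2f (%.2f–%.2f)", mean(sub$dsc), min(sub$dsc),
                       max(sub$dsc)))
  # an organ absent from one version renders as a dash
  gm2 <- gm[!(gm$organ == "rectum" & gm$version == "new"), ]
  st2 <- version_stat_table(gm2, "old", "new")
  tab2 <- build_summary_table(st2)
  expect_equal(tab2$dsc_new[tab2$organ == "rectum"], "–")
})

test_that("ground-truth metrics cover each version and exclude organs without GT", {
  g <- geom_iso(16)
  s <- sphere_mask(g, c(8, 8, 8), 4)
  s2 <- sphere_mask(g, c(9, 8, 8), 4)
  sets <- list(
    structure_set("P1", "old", list(bladder = s, rectum = s), g),
    structure_set("P1", "new", list(bladder = s2, rectum = s), g),
    structure_set("P1", "ground_truth", list(bladder = s), g))
  p <- match_structures(sets)
  gm <- ground_truth_metrics(p, "ground_truth")
  expect_setequal(unique(gm$organ), "bladder")  # rectum has no ground truth
  expect_equal(attr(gm, "excluded")$organ, "rectum")
  old_row <- gm[gm$version == "old", ]
  expect_equal(old_row$dsc, 1)
  expect_equal(old_row$hd_mm, 0)
  expect_error(ground_truth_metrics(p, "expert"), "absent")
})
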