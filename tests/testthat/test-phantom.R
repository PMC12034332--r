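small_spec <- function(n = 3, seed = 7, jitter = 2) {
  phantom_spec(n_patients = n, seed = seed,
               geometry = image_geometry(c(48, 48, 30), c(1, 1, 2)),
               organs = list(
                 organ_shape("bladder", "sphere", c(16, 16, 30), 8),
                 organ_shape("prostate", "sphere", c(32, 32, 20), 6),
                 organ_shape("rectum", "tube", c(32, 16, 30), c(5, 32))),
               inter_patient_jitter_mm = jitter)
}

test_that("identical (spec, seed) pairs generate bit-identical cohorts", {
  c1 <- generate_cohort(small_spec())
  c2 <- generate_cohort(small_spec())
  expect_length(c1, 3)
  for (i in 1:3)
    for (org in names(c1[[i]]$structures))
      expect_identical(c1[[i]]$structures[[org]]$voxels,
                       c2[[i]]$structures[[org]]$voxels)
  # a different seed changes at least one mask
  c3 <- generate_cohort(small_spec(seed = 8))
  expect_false(all(vapply(1:3, function(i)
    identical(c1[[i]]$structures$bladder$voxels,
              c3[[i]]$structures$bladder$voxels), TRUE)))
})

test_that("zero jitter collapses the cohort to identical patients", {
  c0 <- generate_cohort(small_spec(jitter = 0))
  expect_identical(c0[[1]]$structures$rectum$voxels,
                   c0[[3]]$structures$rectum$voxels)
})

test_that("a digitized sphere's voxel volume is within 5% of the analytic volume", {
  g <- image_geometry(c(32, 32, 32), c(1, 1, 1))
  m <- segqa:::make_shape_mask(organ_shape("s", "sphere", c(16, 16, 16), 10), g)
  expect_lt(abs(mask_volume_mm3(m) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
})

test_that("an organ escaping the volume after jitter is an error naming the organ", {
  spec <- phantom_spec(n_patients = 2, seed = 1,
                       geometry = image_geometry(c(20, 20, 10), c(1, 1, 2)),
                       organs = list(organ_shape("bladder", "sphere",
                                                 c(10, 10, 9), 8)),
                       inter_patient_jitter_mm = 3)
  expect_error(generate_cohort(spec), "bladder")
})

test_that("every perturbation kind changes at least one voxel at probability 1", {
  cohort <- generate_cohort(small_spec(n = 2))
  kinds <- list(
    perturbation("bladder", "translate", magnitude = 2, axis = "x"),
    perturbation("bladder", "dilate", magnitude = 1),
    perturbation("bladder", "erode", magnitude = 1),
    perturbation("rectum", "truncate_slices", magnitude = 1, end = "inferior"),
    perturbation("rectum", "extend_slices", magnitude = 1, end = "superior"),
    perturbation("bladder", "add_isolated_blob", offset_mm = c(20, 20, 0),
                 blob_radius_mm = 3),
    perturbation("rectum", "carve_overlap", other_organ = "bladder"))
  for (p in kinds) {
    out <- apply_perturbations(cohort, list(p))
    changed <- !identical(out[[1]]$structures[[p$organ]]$voxels,
                          cohort[[1]]$structures[[p$organ]]$voxels)
    if (p$kind == "carve_overlap") {
      # carving only changes voxels when the organs overlap; check the identity
      expect_identical(out[[1]]$structures$rectum$voxels,
                       cohort[[1]]$structures$rectum$voxels &
                         !cohort[[1]]$structures$bladder$voxels)
    } else {
      expect_true(changed, label = paste("kind", p$kind, "changed voxels"))
    }
  }
  # kind none is bit-identical
  out0 <- apply_perturbations(cohort, list(perturbation("bladder", "none")))
  expect_identical(out0[[1]]$structures$bladder$voxels,
                   cohort[[1]]$structures$bladder$voxels)
  expect_equal(out0[[1]]$version_label, "new")
})

test_that("slice operations respect their arithmetic and bounds", {
  cohort <- generate_cohort(small_spec(n = 1, jitter = 0))
  rec <- cohort[[1]]$structures$rectum
  occ <- which(apply(rec$voxels, 3, any))
  tru <- apply_perturbations(cohort, list(
    perturbation("rectum", "truncate_slices", magnitude = 2, end = "inferior")))
  occ_t <- which(apply(tru[[1]]$structures$rectum$voxels, 3, any))
  expect_equal(occ_t, occ[-(1:2)])
  ext <- apply_perturbations(cohort, list(
    perturbation("rectum", "extend_slices", magnitude = 2, end = "superior")))
  occ_e <- which(apply(ext[[1]]$structures$rectum$voxels, 3, any))
  expect_equal(occ_e, c(occ, max(occ) + 1:2))
  expect_identical(ext[[1]]$structures$rectum$voxels[, , max(occ) + 1],
                   rec$voxels[, , max(occ)])  # copies the terminal slice
  expect_error(apply_perturbations(cohort, list(
    perturbation("rectum", "truncate_slices", magnitude = 99,
                 end = "inferior"))), "slice count")
})

test_that("isolated blobs are disjoint and carve DSC follows voxel counts", {
  cohort <- generate_cohort(small_spec(n = 1, jitter = 0))
  out <- apply_perturbations(cohort, list(
    perturbation("bladder", "add_isolated_blob", offset_mm = c(20, 20, 0),
                 blob_radius_mm = 3)))
  old <- cohort[[1]]$structures$bladder$voxels
  new <- out[[1]]$structures$bladder$voxels
  blob <- new & !old
  expect_gt(sum(blob), 0)
  expect_false(any(blob & old))
  # an overlapping blob placement is rejected
  expect_error(apply_perturbations(cohort, list(
    perturbation("bladder", "add_isolated_blob", offset_mm = c(2, 0, 0),
                 blob_radius_mm = 3))), "isolated")

  # carve: DSC drop equals 2(|A| - |overlap|) / (2|A| - |overlap|)
  carved <- apply_perturbations(cohort, list(
    perturbation("rectum", "carve_overlap", other_organ = "bladder")))
  A <- cohort[[1]]$structures$rectum
  C <- carved[[1]]$structures$rectum
  ov <- mask_count(A) - mask_count(C)
  if (ov > 0) {
    expect_equal(dice(A, C),
                 2 * (mask_count(A) - ov) / (2 * mask_count(A) - ov))
  }
})

test_that("perturbations selecting organs absent from the cohort fail loudly", {
  cohort <- generate_cohort(small_spec(n = 1))
  expect_error(apply_perturbations(cohort, list(perturbation("liver", "dilate",
                                                             magnitude = 1))),
               "not present")
})

test_that("the bundled three-version scenario is reproducible with a stable manifest", {
  s1 <- scenario_update_qa(seed = 3, n_patients = 2)
  s2 <- scenario_update_qa(seed = 3, n_patients = 2)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$sets$new[[1]]$structures$rectum$voxels,
                   s2$sets$new[[1]]$structures$rectum$voxels)
  expect_setequal(names(s1$sets), c("old", "new", "ground_truth"))
  # old is the ground truth relabelled: the update is the only difference
  expect_identical(s1$sets$old[[2]]$structures$brain$voxels,
                   s1$sets$ground_truth[[2]]$structures$brain$voxels)
  expect_false(identical(s1$sets$new[[2]]$structures$brain$voxels,
                         s1$sets$ground_truth[[2]]$structures$brain$voxels))
})
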