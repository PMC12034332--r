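test_that("geometry constructor enforces positive spacing and shape", {
  expect_error(image_geometry(c(10, 10, 10), c(1, 0, 2)), "strictly positive")
  expect_error(image_geometry(c(10, 10, 10), c(1, -1, 2)), "strictly positive")
  expect_error(image_geometry(c(10, 10), c(1, 1, 1)), "voxel counts")
  g <- image_geometry(c(4, 5, 6), c(1, 2, 2.5), origin = c(-1, 0, 3))
  expect_equal(slice_planes(g), 3 + (0:5) * 2.5)
})

test_that("axis-aligned square with vertices on voxel-centre lines rasterises exactly", {
  g <- image_geometry(c(32, 32, 3), c(1, 1, 2))
  ct <- rt_contour("bladder", list(list(
    z = 2, xy = rbind(c(5, 5), c(25, 5), c(25, 25), c(5, 25)))))
  m <- rasterize(ct, g)
  # half-open convention: left/bottom edges in, right/top out -> 20 x 20
  expect_equal(mask_count(m), 400)
  expect_true(all(which(apply(m$voxels, 3, any)) == 2))
  expect_equal(sum(m$voxels[, , 2][6:25, 6:25]), 400)
})

test_that("rasterisation agrees with the even-odd point-in-polygon oracle", {
  set.seed(41)
  g <- image_geometry(c(24, 24, 1), c(1, 1, 1))
  xc <- axis_centers(g, 1); yc <- axis_centers(g, 2)
  for (case in 1:8) {
    # random simple polygon: convex hull of random points, off-lattice
    pts <- cbind(runif(12, 1.3, 21.7), runif(12, 1.3, 21.7))
    hull <- pts[chull(pts), , drop = FALSE]
    ct <- rt_contour("x", list(list(z = 0, xy = hull)))
    m <- rasterize(ct, g)
    expect_identical(m$voxels[, , 1], rasterize_oracle(hull, xc, yc))
  }
})

test_that("multiple rings per slice follow the even-odd rule", {
  g <- image_geometry(c(40, 40, 1), c(1, 1, 1))
  ring1 <- list(z = 0, xy = rbind(c(2, 2), c(12, 2), c(12, 12), c(2, 12)))
  ring2 <- list(z = 0, xy = rbind(c(20, 20), c(30, 20), c(30, 30), c(20, 30)))
  m <- rasterize(rt_contour("rectum", list(ring1, ring2)), g)
  expect_equal(mask_count(m), 200)  # two disjoint 10x10 regions
  sl <- m$voxels[, , 1]
  expect_true(any(sl[3:12, 3:12]) && any(sl[21:30, 21:30]))
  expect_false(any(sl[14:19, ]))   # gap between the regions: 2 components

  # ring inside ring carves a hole (even-odd)
  outer_ring <- list(z = 0, xy = rbind(c(2, 2), c(22, 2), c(22, 22), c(2, 22)))
  inner_ring <- list(z = 0, xy = rbind(c(8, 8), c(16, 8), c(16, 16), c(8, 16)))
  m2 <- rasterize(rt_contour("x", list(outer_ring, inner_ring)), g)
  expect_equal(mask_count(m2), 20 * 20 - 8 * 8)
})

test_that("ring slice assignment: nearest plane, half-spacing tie to lower slice, far ring errors", {
  g <- image_geometry(c(10, 10, 4), c(1, 1, 2))  # planes at z = 0, 2, 4, 6
  sq <- rbind(c(1, 1), c(8, 1), c(8, 8), c(1, 8))
  near <- rasterize(rt_contour("x", list(list(z = 2.4, xy = sq))), g)
  expect_equal(which(apply(near$voxels, 3, any)), 2L)
  tie <- rasterize(rt_contour("x", list(list(z = 3, xy = sq))), g)
  expect_equal(which(apply(tie$voxels, 3, any)), 2L)  # tie -> lower index
  expect_error(rasterize(rt_contour("x", list(list(z = 7.2, xy = sq))), g),
               "half a slice spacing")
})

test_that("rasterised volume converges to analytic area x thickness as spacing shrinks", {
  # 17.3 x 9.1 mm rectangle, area known analytically
  xy <- rbind(c(1.05, 1.05), c(18.35, 1.05), c(18.35, 10.15), c(1.05, 10.15))
  vol_at <- function(sp) {
    g <- image_geometry(c(ceiling(24 / sp), ceiling(16 / sp), 1), c(sp, sp, 2))
    mask_volume_mm3(rasterize(rt_contour("x", list(list(z = 0, xy = xy))), g))
  }
  true_vol <- 17.3 * 9.1 * 2
  err <- abs(c(vol_at(1), vol_at(0.25)) - true_vol)
  expect_lt(err[2], err[1])           # monotone error decrease
  expect_lt(err[2] / true_vol, 0.05)  # and small at the finer spacing
})

test_that("structure sets round-trip bit-exactly through both on-disk layouts", {
  g <- geom_iso(16)
  a <- random_blob_mask(g)
  b <- sphere_mask(g, c(8, 8, 8), 4)
  ss <- structure_set("P7", "old", list(Bladder = a, Rectum = b), g)

  d1 <- file.path(tempdir(), "ss_dir")
  write_structure_set(ss, d1, format = "dir")
  back <- read_structure_set(d1)
  expect_equal(back$patient_id, "P7")
  expect_equal(back$version_label, "old")
  expect_identical(back$structures$Bladder$voxels, a$voxels)
  expect_identical(back$structures$Rectum$voxels, b$voxels)
  expect_equal(back$geometry$spacing, g$spacing)

  # labelmap layout requires disjoint masks
  disj <- binary_mask(b$voxels & !a$voxels, g)
  ss2 <- structure_set("P8", "new", list(Bladder = a, Rectum = disj), g)
  d2 <- file.path(tempdir(), "ss_lab")
  write_structure_set(ss2, d2, format = "labelmap")
  back2 <- read_structure_set(file.path(d2, "masks.nii.gz"))
  expect_identical(back2$structures$Bladder$voxels, a$voxels)
  expect_identical(back2$structures$Rectum$voxels, disj$voxels)

  # overlapping masks are rejected by the labelmap writer
  expect_error(write_structure_set(ss, file.path(tempdir(), "ss_bad"),
                                   format = "labelmap"), "disjoint")
})

test_that("empty structures are preserved with a warning, never dropped", {
  g <- geom_iso(12)
  ss <- structure_set("P1", "old",
                      list(full = sphere_mask(g, c(6, 6, 6), 3),
                           gone = empty_mask(g)), g)
  d <- file.path(tempdir(), "ss_empty")
  write_structure_set(ss, d)
  expect_warning(back <- read_structure_set(d), "empty")
  expect_true("gone" %in% names(back$structures))
  expect_true(mask_is_empty(back$structures$gone))
})

test_that("duplicate organ names and missing geometry are hard errors", {
  g <- geom_iso(8)
  m <- sphere_mask(g, c(4, 4, 4), 2)
  expect_error(structure_set("P1", "old", list(a = m, a = m), g), "duplicate")

  # sidecar without geometry block and no geometry_source -> missing geometry
  d <- file.path(tempdir(), "ss_nogeom")
  dir.create(d, showWarnings = FALSE)
  jsonlite::write_json(list(patient_id = "P1", version_label = "old",
                            labels = list(`1` = "bladder")),
                       file.path(d, "masks.json"), auto_unbox = TRUE)
  img <- RNifti::asNifti(array(1L, c(8, 8, 8)))
  RNifti::writeNifti(img, file.path(d, "masks.nii.gz"))
  expect_error(read_structure_set(file.path(d, "masks.nii.gz")),
               "missing geometry")
  # supplying the geometry externally repairs the read
  back <- read_structure_set(file.path(d, "masks.nii.gz"),
                             geometry_source = g)
  expect_equal(names(back$structures), "bladder")
  expect_equal(mask_count(back$structures$bladder), 512)
})
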