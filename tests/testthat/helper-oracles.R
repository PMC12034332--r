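# Independent brute-force oracles, deliberately written as plain scalar /
# per-point code so they share no implementation with the package paths
# they check.

# Even-odd point-in-polygon by scalar crossing count. Same half-open
# boundary convention as the rasteriser (bottom/left inclusive), but test
# polygons are generated off the voxel-centre lattice so boundary cases
# never decide a comparison.
pip_oracle <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- FALSE
  for (e in seq_len(n)) {
    x1 <- xy[e, 1]; y1 <- xy[e, 2]
    x2 <- xy[e %% n + 1, 1]; y2 <- xy[e %% n + 1, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

rasterize_oracle <- function(xy, xc, yc) {
  out <- matrix(FALSE, length(xc), length(yc))
  for (i in seq_along(xc))
    for (j in seq_along(yc))
      out[i, j] <- pip_oracle(xc[i], yc[j], xy)
  out
}

# Per-point nearest-neighbour distances: squared terms added x, y, z in
# order as plain doubles (no extended-precision accumulation), min taken
# over squared distances, sqrt applied once.
min_dists_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

hausdorff_oracle <- function(a, b) {
  max(max(min_dists_oracle(a, b)), max(min_dists_oracle(b, a)))
}

mdta_oracle <- function(a, b) {
  (sum(min_dists_oracle(a, b)) + sum(min_dists_oracle(b, a))) /
    (nrow(a) + nrow(b))
}

# Surface definition applied voxel by voxel (6-face adjacency, volume edge
# counts as outside), as mm voxel centres.
surface_oracle <- function(m) {
  v <- m$voxels; d <- dim(v)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!v[i, j, k]) next
    nb <- c(
      if (i > 1) v[i - 1, j, k] else FALSE,
      if (i < d[1]) v[i + 1, j, k] else FALSE,
      if (j > 1) v[i, j - 1, k] else FALSE,
      if (j < d[2]) v[i, j + 1, k] else FALSE,
      if (k > 1) v[i, j, k - 1] else FALSE,
      if (k < d[3]) v[i, j, k + 1] else FALSE)
    if (!all(nb))
      pts <- rbind(pts, (c(i, j, k) - 1) * m$geometry$spacing +
                     m$geometry$origin)
  }
  pts
}

# Full 2^n enumeration of the signed-rank null: every sign assignment of
# the observed |differences|, two-sided p as twice the smaller tail.
signrank_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vals <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vals <= v_obs + 1e-12), mean(vals >= v_obs - 1e-12)))
}

# Equal-radius sphere pair: analytic DSC from the lens intersection volume
# V_lens = pi (4r + d) (2r - d)^2 / 12, V_sphere = 4 pi r^3 / 3.
sphere_dsc_analytic <- function(r, d) {
  if (d >= 2 * r) return(0)
  ((4 * r + d) * (2 * r - d)^2 / 12) / (4 * r^3 / 3)
}

# --- fixture builders ----------------------------------------------------

geom_iso <- function(n = 24, sp = 1) image_geometry(rep(n, 3), rep(sp, 3))

mask_from_indices <- function(g, idx) {
  v <- array(FALSE, g$shape)
  v[idx] <- TRUE
  binary_mask(v, g)
}

random_blob_mask <- function(g, n_seeds = 3, grow = 2) {
  v <- array(FALSE, g$shape)
  d <- g$shape
  for (s in seq_len(n_seeds)) {
    c0 <- sapply(d, function(n) sample(seq(3, n - 2), 1))
    r <- sample(2:4, 1)
    xs <- pmax(1, c0[1] - r):pmin(d[1], c0[1] + r)
    ys <- pmax(1, c0[2] - r):pmin(d[2], c0[2] + r)
    zs <- pmax(1, c0[3] - r):pmin(d[3], c0[3] + r)
    v[xs, ys, zs] <- v[xs, ys, zs] |
      (array(stats::runif(length(xs) * length(ys) * length(zs)),
             c(length(xs), length(ys), length(zs))) < 0.7)
  }
  binary_mask(v, g)
}

sphere_mask <- function(g, center, r) {
  make_triple_shape <- organ_shape("s", "sphere", center, r)
  segqa:::make_shape_mask(make_triple_shape, g)
}

cube_mask <- function(g, x0, nx = 10, ny = 10, nz = 10) {
  v <- array(FALSE, g$shape)
  v[x0:(x0 + nx - 1), 1:ny, 1:nz] <- TRUE
  binary_mask(v, g)
}

# tiny two-version cohort builder for screening/report tests
tiny_sets <- function(version_label, masks, patient_id = "P1", g = geom_iso()) {
  structure_set(patient_id, version_label, masks, g)
}
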