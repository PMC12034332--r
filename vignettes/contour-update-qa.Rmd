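---
title: "Methods: geometric screening of auto-segmentation updates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric screening of auto-segmentation updates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Deep-learning auto-segmentation (DLS) software delineates organs at risk on
planning CT, and vendors update it regularly — retraining models, changing
post-processing, or altering how overlapping structures are handled. The
update's effect on contours is usually undocumented, yet contours drive
dose optimisation. Reviewing all organs of all patients against expert
contours after each update is impractical, and comparing each version to
expert ground truth directly can mask changes: two versions can differ from
each other while sitting at similar distances from the expert contour.

`segqa` therefore treats update QA as a *two-stage screening* problem:

1. **Screen** the post-update structure set against the pre-update one, on
   the same patients and the same CT grids, with three geometric indices
   (DSC, maximum surface Hausdorff distance, mean distance to agreement).
   Because both inputs come from software on identical images, the null
   expectation is *exact identity*; any deviation is an effect of the
   update. An organ is flagged as notably modified when any single index
   crosses its criteria threshold.
2. **Evaluate** only the flagged organs against expert ground-truth
   contours, per version, and test per-organ differences between versions
   with the paired Wilcoxon signed-rank test at alpha 0.05.

The assumptions this encodes: all versions of a patient's structures share
one image geometry (cross-geometry comparison is rejected, never silently
resampled); slice spacing is constant; and the contour set, not the image,
is the object of interest (no intensities are modelled anywhere).

## Indices and their numerical dialect

Masks are voxelisations of planar contours by the even-odd rule at voxel
centres, with a half-open boundary convention (bottom/left edges inside) so
abutting rings tile the grid without double counting. Contour rings attach
to the nearest slice plane; a ring exactly half a spacing from two planes
goes to the lower-index slice (RT contours normally coincide with CT
planes, so this tie-break only affects adversarial inputs; a ring farther
than half a spacing from every plane is an error).

Surface distances are measured between *boundary-voxel centres*: the
surface of a mask is the set of true voxels with at least one of six face
neighbours false or outside the volume. This point-cloud dialect is chosen
over signed distance fields or meshes because it is deterministic and
exactly checkable against an O(n²) brute-force oracle — the package's
accelerated C++ nearest-neighbour kernel is required by the test suite to
reproduce that oracle bit-for-bit (the oracle accumulates squared terms in
plain double precision for that reason; R's `colSums` long-double
accumulation differs by 1 ulp).

Two conventions the field leaves open are fixed and isolated here:

* **HD is the full symmetric maximum**, not a percentile variant: the
  strict screening threshold (0.2 cm, one slice) is only meaningful for
  the maximum.
* **MDTA is the pooled symmetric average** (one division by
  `|S_A| + |S_B|`), not the mean of the two directed averages. The
  alternative is a one-line variant of a single function
  (`mean_distance_to_agreement`) if a site prefers it.

A pair with an empty mask yields `undefined_empty` rather than an infinite
HD: a vanished organ must surface as an explicit flag, not as a numeric
artefact. Identical masks short-circuit to (DSC 1, MDTA 0, HD 0), which is
exact, and keeps screening of mostly-unchanged cohorts fast.

## Criteria and the flagging rule

Criteria A (strict: DSC 0.99, MDTA 0.05 cm, HD 0.2 cm) asks "did the
update change this organ at all?" — 0.2 cm is one slice on a typical 2 mm
protocol. Criteria B (standard: DSC 0.9, MDTA 0.2 cm, HD 1.0 cm) encodes
the conventional near-identity reading. Flagging is the OR over the three
indices; equality with a threshold does **not** violate, because criteria
are quoted as target values rather than open intervals. Under the shipped
presets A strictly dominates B (every B flag is an A flag), which the test
suite checks on 10⁴ random triples.

Organ-level aggregation defaults to the mean triple across patients
(`per_organ_mean`, matching the per-organ bar-summary reading); the
`per_patient` mode — flag if *any* patient violates — is kept because a
single-patient catastrophe (an isolated mis-segmented region tens of mm
away) can be invisible in a mean. Thresholds are configured in cm in the
user-facing YAML (the unit criteria are usually quoted in) and converted
to mm once at parse time; everything internal is mm.

## Preprocessing: the anchored crop

Superior/inferior delineation extent of the rectum varies legitimately
between observers and versions, which would contaminate the version
comparison. The shipped rule crops the rectum to a z window of 1 cm above
and below the prostate. Two open choices are fixed as defaults and exposed
as configuration:

* the window derives from **one designated version's** anchor (ground
  truth if present, else the first version) and that same window applies
  to every version — anchoring each version on its own prostate would
  confound the comparison;
* window bounds are **inclusive**, so 10 mm margins on 2 mm slices keep
  exactly five slices beyond the anchor on each side.

Cropping is idempotent and never adds voxels (both property-tested). A
target left empty by the crop is an empty mask, flagged downstream, not an
error.

## The Wilcoxon stage

Per organ and per index, patients with computed (non-empty, non-missing)
triples in *both* versions are paired; means and ranges are reported over
exactly those patients. The test is two-sided (updates can improve or
degrade), with no multiple-testing correction by default (raw p < 0.05 per
organ and index is the convention this workflow follows; Holm is available
as an option).

Version-identical contours produce many exact zero differences, so the
zero policy is explicit:

* `drop` (default, the classic test) discards zeros before ranking; its
  null is exact via the signed-rank distribution when the effective n is
  at most 25 with no tied ranks, and a tie-corrected, continuity-corrected
  normal approximation otherwise (mirroring, and cross-checked against,
  `stats::wilcox.test`).
* `keep` ranks zeros with everything else (zeros contribute nothing to
  the statistic); its null is enumerated exactly over all 2^m sign
  assignments for m ≤ 16 nonzero differences, with a zero- and
  tie-corrected normal approximation beyond.

If every difference is zero the p-value is 1 (no evidence of change); if
dropping zeros leaves nothing, the result is marked not-testable rather
than inventing a p.

One scale property deserves an explicit caveat. The signed-rank statistic
ranks the *magnitudes* of paired differences, so its p-value is invariant
under positive affine rescaling of both members, and under arbitrary
monotone maps only when all differences share one sign (the statistic is
then pinned at an extreme). It is **not** invariant under general
nonlinear monotone transforms — that property belongs to tests that rank
values rather than differences (the sign test, the two-sample rank-sum
test). The test suite asserts the invariances that hold; base R's
`wilcox.test` exhibits the identical behaviour.

## The synthetic phantom: what it emulates, what it does not

Clinical structure sets cannot ship with a package, so every pipeline
stage is exercised on a deterministic phantom cohort: analytic primitives
(spheres, ellipsoids, tubes, boxes) whose volumes and mutual distances
are known in closed form, jittered per patient. Determinism is strict —
identical (spec, seed) pairs generate bit-identical cohorts, and every
perturbation selects its affected patients from its own seed.

The perturbation taxonomy mirrors the failure modes updates actually
produce: whole-slice extension at one end (`extend_slices`), inferior
truncation (`truncate_slices`), a spurious disconnected region far from
the organ (`add_isolated_blob`), a neighbouring organ's overlap newly
excluded (`carve_overlap`), plus generic translate/dilate/erode.

`scenario_update_qa()` bundles a three-version fixture with a manifest of
organs that must / must not be flagged under strict criteria:

* brain: carved by the brainstem overlap (flagged under both criteria);
* rectum: truncated two slices inferiorly in every patient, plus an
  isolated blob 40 mm away in exactly one patient;
* lens and optic nerve: extended one slice superiorly;
* bladder: translated bodily by 1 mm in-plane;
* prostate, brainstem, seminal vesicle: untouched (must sit at exact
  identity).

Design choices worth recording:

* The fixture grid is 96×96×48 at (1, 1, 2.5) mm. The 2.5 mm slice makes
  a one-slice extension (2.5 mm) *strictly* exceed the 2 mm strict HD
  threshold — equality would not violate. The default `phantom_spec`
  grid keeps 2.0 mm slices, the typical planning-CT protocol.
* The bladder fault is a 1 mm translation rather than a dilation: on this
  grid a 1-voxel isotropic dilation of a mid-size organ drops DSC below
  0.9 and would flag under the standard criteria too, whereas the
  intended signature — "the outline does not match, DSC ≈ 0.94" — is an
  A-only flag.
* The pre-update version equals the ground truth: the pre-update model is
  taken as previously validated, so every geometric change in the fixture
  is attributable to the simulated update, and the manifest arithmetic is
  exact.

What the phantom does *not* emulate: CT intensities, deformable or
realistic anatomy, inter-observer variability in the ground truth, and
implanted devices (e.g. rectum–prostate spacers). A green suite therefore
demonstrates the *pipeline arithmetic* — metric correctness, flag logic,
statistics — on controlled geometry; it does not certify performance on
clinical anatomy.

## Problem sizes and numerical tolerances

The shipped test and acceptance workloads were sized for a desk machine:
metric-oracle equivalence on 200 random mask pairs within 24³ grids
(exact equality, tolerance zero); sphere-pair DSC against the closed-form
lens-intersection volume at 2 mm and 1 mm spacings (voxelisation error
must shrink with spacing and be below 0.02 at 1 mm); criteria dominance on
10⁴ random triples; 2 000 null simulations for the type-I calibration; and
the end-to-end fixture at 25 patients.

The type-I simulation uses series of 14 pairs: the exact signed-rank test
is discrete, and its achievable two-sided level at alpha 0.05 depends on n
(0.039 at n = 8, 0.0494 at n = 14). n = 14 was chosen at design time so
that the empirical rejection rate can fall within binomial 95% bounds of
the nominal level.

Degenerate inputs are handled by explicit contract rather than tolerance:
empty masks propagate `undefined_empty`; empty anchors are errors; rings
off the slice lattice are errors; truncating more slices than an organ has
is an error; a blob that touches its organ is an error (it must be an
isolated region).

## Known limitations

* No DICOM parsing: structure sets are exchanged as NIfTI mask volumes
  with JSON sidecars (one file per organ, or a label map for disjoint
  structures). Planar-contour objects are supported in memory and
  rasterised on write.
* Surface metrics are voxel-centre point-cloud metrics; systems that
  compute mesh-based or signed-distance metrics will differ by up to
  about a voxel diagonal near curved boundaries.
* Only constant slice spacing is supported, and masks being compared must
  share one geometry; nothing is resampled.
* The Wilcoxon stage models no rater variability in the ground truth and
  applies no multiplicity correction by default.
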