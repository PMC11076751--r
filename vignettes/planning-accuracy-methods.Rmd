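---
title: "Scoring neurosurgical planning accuracy: models, conventions, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring neurosurgical planning accuracy: models, conventions, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioplan)
```

# Overview

cranioplan scores surgical-planning drawings — tumor projection painting,
linear and U-shaped incisions, burr holes, and craniotomy borders — against
the orthographic silhouette of an underlying tumor, and compares paired
pre/post assessments (AA1 after MRI-only planning, AA2 after planning with a
patient-specific 3D model) over a cohort. Because the study data this
design comes from (one parasagittal meningioma case, 38 participants) are
not distributed, the package also generates the inputs: a layered synthetic
head phantom and simulated annotation cohorts with a controllable error
structure. This vignette records the model, the measurement conventions,
the calibration of the simulator, and the numerical choices, so that every
number the package produces has a stated definition.

# The assessment plane and the measurement model

All metrics are planar. A single orthographic *assessment plane* is fixed
with origin at the tumor center and normal along the phantom's projection
axis (superior, +z, by default); the tumor silhouette and every drawing are
projected into it, and areas, overlaps, distances, and margins are computed
there. The alternative — measuring areas geodesically on the curved scalp —
is deliberately out of scope: a common plane makes all quantities
well-defined and mutually comparable, at the cost of a mild foreshortening
of drawings far from the projection axis. For the default geometry (a
tumor under a gently curved superior scalp patch) this distortion is small,
but it is a modeling convention, not a measured fact; sensitivity to it can
be explored by changing `projection_axis`.

## Rasterized reference semantics

Areas and overlaps are measured by counting grid-cell centers inside a
region, on a grid anchored to the global mm lattice (cells at
(k + 1/2) · pitch). Two consequences are worth stating:

* **Conservation is exact.** Painted area, covered area, and excess are
  counted on one shared grid, so painted = covered + excess holds exactly
  at the cell level, not merely approximately.
* **Resolution is explicit.** The default `raster_pitch` of 0.25 mm keeps
  the worst-case boundary error below roughly pitch · perimeter ≈ 1% for
  regions at the phantom's scale (the tests verify ≤ 0.5% in practice for
  ellipse fixtures, and that the error shrinks under pitch halving). All
  user-facing functions accept a `pitch` argument; coarser values (0.5 or
  1 mm) are appropriate for replication loops.

Exact polygon clipping would be a legitimate alternative engine; the raster
is the package's reference semantics because every downstream identity
(conservation, coverage bounds) is then true by construction.

Regions use even-odd ring semantics: disjoint rings union, nested rings
punch holes. Self-intersecting rings are rejected at construction.

## Metric conventions

* **Percent tumor coverage** = 100 · |P ∩ T| / |T|, with T the tumor
  silhouette and P the painted region; **excess coverage** = |P| − |P ∩ T|.
* **Tumor epicenter** = area centroid of T (the reference defines only
  "center of tumor"; the centroid is the unique convention that is
  translation-equivariant and agrees with the center for symmetric
  silhouettes). **Incision deviation** is the *minimum* distance from the
  epicenter to the drawn polyline, not the distance to its midpoint: an
  incision passing through the epicenter scores 0, matching clinical
  intent.
* **Edge margin** mᵢ: signed distance from the silhouette boundary to the
  edge midpoint, measured along the ray from the epicenter through that
  midpoint; positive outside. This "midpoint-ray" rule mimics the visual
  judgment "this edge sits N mm outside the border" and is deterministic.
  A segment-minimum alternative (`convention = "segment-min"`) is provided
  for sensitivity analysis; the midpoint-ray rule is the reference.
* **Scores.** An edge scores 1 when mᵢ lies in the **closed** band
  [5, 15] mm ("within 5–15 mm": ties included). The craniotomy score is
  the sum over the four edges (0–4). The U-incision is an open polyline
  with four corners; its three limbs are scored like edges and the
  imaginary line closing the flap base contributes the fourth point. An
  edge whose centroid ray misses the silhouette (pathological placement)
  scores 0 with a warning rather than failing the whole assessment.
* **Margin deviation sum** = Σ |mᵢ − 10| mm. The acceptable standard
  border is taken as 10 mm — the center of the scoring band — since the
  reference does not define it; it is configurable (`standard_margin`).
  Note the deliberate non-equivalence with the score: a sum of 20 mm can
  come from four 5 mm deviations (score 4) or one 20 mm deviation
  (score 3); the tests pin this down.
* **Burr holes** are recorded in the data model and files but never
  scored; no burr-hole metric exists in the assessment.

# The synthetic phantom

The phantom is analytic: an ellipsoidal scalp (semi-axes 90 × 75 × 80 mm),
a 6 mm skull shell starting 6 mm inward, and an ellipsoidal tumor centered
superiorly on the midline at (0, 0, 35) mm. The tumor's in-plane semi-axes
are fixed at 31.2 × 27.72 mm so its silhouette area is π · 31.2 · 27.72 ≈
2,717 mm², the calibrated reference area; the third semi-axis (20 mm,
depth) is unconstrained by any planar metric. Only the projected area is
dictated by the reference case — the axis ratio and all other dimensions
are anatomically plausible reconstructions, not measured values.

Meshes are subdivided icosahedra scaled to the ellipsoids (watertight and
convex by construction; silhouettes of convex meshes are computed exactly
as convex hulls of projected vertices). `voxelize()` samples the analytic
geometry into a label volume (0 background, 1 scalp, 2 skull, 3 brain
space, 4 tumor; priority tumor > skull > scalp), refusing pitches at which
the tumor would span fewer than 8 voxels per axis. `extract_surface()`
recovers meshes from label volumes by marching tetrahedra on the Kuhn
6-tetrahedron decomposition, after smoothing the binary indicator with a
separable 1-2-1 kernel (2 passes by default). The smoothing is essential,
not cosmetic: the isosurface of a *raw* binary indicator is a staircase
whose area overestimates a smooth surface by a resolution-independent
factor (about 27% for a sphere), while the smoothed indicator's 0.5-level
surface converges to the true surface — the tests require sphere area and
volume within 2% at 0.5 mm pitch and monotone error decay over pitch
halvings. The Kuhn decomposition tiles consistently across the voxel
lattice, so extracted meshes are watertight.

# The cohort simulator

## What it emulates

Each simulated participant draws once per assessment. The error structure
is a `skill_profile` per group × assessment:

* **Painted region**: the true silhouette scaled uniformly by
  √(area factor) about its centroid and translated. The displacement is
  controlled either directly (`paint_shift`, mm) or — in the calibrated
  defaults — through a target-coverage distribution converted to a
  displacement with the circle-lens closed form after affine normalization
  (the map that sends the silhouette to the unit circle sends the scaled
  copy to a circle of radius √f, so ellipse–ellipse overlap reduces to the
  two-circle lens). Perturbing the true silhouette keeps closed-form
  oracles available; free-form boundary noise is an extension hook, not a
  current feature.
* **Linear incision**: an 80 mm segment whose minimum distance to the
  epicenter equals the sampled offset, at a uniformly random orientation.
* **Craniotomy**: a quadrilateral realizing sampled edge margins (next
  section). **U-incision**: the same construction with its own four margin
  draws, with the base edge left open as the imaginary line. **Burr
  holes**: the four craniotomy corners.
* Drawings are lifted onto the scalp/bone surfaces by ray casting along
  the projection axis, so annotation files carry both plane and 3D
  coordinates.

Calibrated default distributions (study-level targets in parentheses):
coverage is Beta on [0, 100] moment-matched per assessment (66.4 ± 26.2
pre, 77.2 ± 17.4 post); the painted-area factor is Gamma moment-matched to
painted area / 2,717 (4,036 ± 1,611 pre, 3,760 ± 1,081 post); incision
offsets are Gamma (16.3 ± 9.6 pre; 8.3 ± 7.9 post for residents). Gamma
rather than truncated normal matters: truncating N(8.3, 7.9) at zero would
inflate its mean to about 10.4 mm, so a truncated-normal simulator could
never recover the nominal post-3D mean. The printed moments are internally
consistent (mean painted − mean excess = mean coverage × 2,717 at both
assessments), which is what makes the joint coverage/painted/excess
calibration possible. Interns receive the pre-assessment incision
distribution at both assessments, since the incision improvement is
reported only for residents; their other components improve like the
residents'. Edge margins are Normal(10, s) per edge with s set so the
expected margin deviation sum matches 57.3 mm (pre) and 47.2 mm (post)
after the feasibility adjustment below.

**Pre/post coupling.** A participant who paints accurately before the 3D
model tends to paint accurately after it. Each error component's pre and
post draws are therefore coupled through a Gaussian copula with latent
correlation `test_retest_rho` (default 0.7, a typical test–retest
correlation for skill measures). This is not a free dial: with independent
draws, the paired design would have roughly 55% power for the coverage
improvement at n = 38, far short of the clearly significant paired results
the marginals come from; at ρ = 0.7 the closed-form noncentrality gives
roughly 90% power, consistent with the design detecting the effect.

**Determinism.** One master seed; participant i draws from substream
seed ⊕ i, recorded in every output. Identical seeds give bit-identical
cohorts; the draw order is fixed so profile composition cannot shift the
stream.

## The margin feasibility constraint

The midpoints of a quadrilateral's four edges always satisfy
M₁ + M₃ = M₂ + M₄ (each side is the average of two corners). Consequently
four *independently* sampled margins are in general not realizable by any
quadrilateral — an instructive geometric fact discovered the hard way. The
generator therefore places the four midpoints on the axis rays at
(boundary + raw margin) and redistributes the parallelogram defect
symmetrically between the two opposite pairs; corners are then
reconstructed from the adjusted midpoints. The *achieved* margin is
approximately 0.75 · raw + 0.25 · raw(opposite edge), i.e. margins become
positively coupled across opposite edges and their SD shrinks by √10 / 4.
The calibrated profiles inflate the raw draw SD by the reciprocal factor,
so the achieved margin deviation sums still target the nominal means. The
achieved margins — computed in closed form for the elliptical silhouette —
are stored with the draws, which is what makes the geometry-free fast path
(`simulate_cohort_metrics()`) agree with full geometric assessment (the
tests bound the discrepancy by the polygonal discretization of the
silhouette, a few hundredths of a millimetre). Raw margins are clamped at
−0.8 × the boundary distance so no edge midpoint collapses onto the
epicenter.

## What passing tests do and do not show

The simulator produces plans whose *marginal metric distributions* and
*pre/post coupling* match the calibration targets, and whose geometry
exactly realizes the sampled parameters (point-mass profiles invert to
their parameters through the full metric pipeline). It does **not**
emulate: free-form painting (painted regions are affine copies of the
silhouette), correlated errors *across* different drawing types within a
participant (a sloppy painter is not made a sloppy craniotomy-drawer
beyond the shared assessment-level profiles), the discrete habits of real
drawing (snapping to sutures or midline), or intra-rater measurement error
of the human assessors. The ordinal score distributions are consequences
of the margin model rather than separately calibrated, so their medians
need not reproduce the reference values even though the margin deviation
sums do; conclusions about real cohorts should rest on the continuous
metrics, which is also what the assessment design itself concluded.

# Statistics

Continuous metrics (areas, percentages, distances) are compared with the
paired t-test and summarized mean ± SD; the ordinal 0–4 scores use the
Wilcoxon matched-pairs signed-rank test and median [IQR]. The `auto`
method applies exactly this mapping — it follows the printed usage rather
than a normality pre-test. Wilcoxon details: zero differences are dropped
before ranking (the count is reported); the exact signed-rank distribution
is used for ≤ 25 nonzero differences without ties, the normal
approximation with continuity and tie correction otherwise; an all-zero
difference vector returns p = 1 flagged as degenerate rather than an
error. Exactness is verified against full 2ⁿ sign enumeration in the
tests. Quartiles use linear interpolation between order statistics
(`quantile()` type 7) so Likert-style `median [q1–q3]` summaries are
reproducible. No multiple-testing correction is applied across the seven
metrics — each comparison is marginal, as in the assessment design — and
the output metadata says so. Stratified comparisons (residents vs
interns) are independent per-stratum analyses with no pooling; strata
with fewer than two complete pairs are skipped with a warning.

# Numerical choices and degenerate inputs

* Raster pitch 0.25 mm default; grid anchored to the mm lattice so
  translated copies of a region share cell geometry.
* Silhouettes of convex meshes: convex hull of projected vertices (exact
  to mesh resolution). Non-convex meshes: triangle-shadow rasterization +
  marching-squares outline at the configured pitch.
* Isosurface: 2 smoothing passes, isolevel 0.5, degenerate (zero-area)
  triangles dropped, coincident vertices welded at 10⁻⁷ mm.
* Tumor meshes use icosphere subdivision 4 (5,120 faces); scalp/skull use
  subdivision 3 — silhouette accuracy only matters for the tumor.
* Zero-area silhouettes are a configuration error; zero-area painted
  regions are legal (coverage 0). One-point polylines, self-intersecting
  rings, and non-simple quadrilaterals are rejected with classed errors.
* Problem sizes in the test-suite replication loops (2,000 null cohorts
  for the type-I check, 200 cohorts for the power check, 200 random region
  pairs for conservation, n = 3,000 participants for moment calibration)
  were chosen to give Monte-Carlo standard errors comfortably below the
  asserted tolerances.

# Known limitations

* Planar metrics ignore scalp curvature (stated convention; geodesic
  measurement is a possible extension).
* The phantom is analytic and smooth; real segmentations produce rougher
  surfaces, which only the isosurface path exercises.
* The paired power of the simulated design depends on `test_retest_rho`,
  which is a modeling assumption, not an estimated quantity.
* Ordinal score distributions are emergent, not calibrated (above).
* `simulate_cohort_metrics()` uses elliptical closed forms for the margin
  adjustment; for user-supplied non-ellipsoidal tumors it is an
  approximation and the geometric path is authoritative.
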