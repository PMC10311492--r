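---
title: "3D fracture mapping of distal femoral fractures: models, parameters, and validation"
author: "fracmap3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D fracture mapping: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracmap3d)
```

## The method

Fracture mapping summarizes where a class of fractures tends to run. For
each patient, the fragments segmented from CT are virtually reduced into
anatomical position, the assembled model is registered to a single
reference bone (the *template*), and two features are traced onto the
template surface: the **fracture lines** — the curves where an interface
between two fragments meets the outer cortex — and the **comminution
footprints** — the cortical surface occupied by small fragments. Counting,
per template vertex, how many of the *n* cases involve that vertex gives a
frequency

$$ f_v = 100 \cdot \frac{c_v}{n} \;\; [\%], \qquad 0 \le c_v \le n, $$

rendered as a heat map: dark blue to dark red for lines, white to black for
comminution. Two conventions anchor the pipeline:

* a fragment belongs to the **comminution zone** when its volume is
  **strictly below 1 cm³** (a fragment of exactly 1.00 cm³ is not
  comminuted);
* a case enters the maps only if its reduced model lies **within 5 mm**
  (inclusive) of the template everywhere — the *spacing gate*.

`fracmap3d` implements this pipeline for AO/OTA 33A (extra-articular
supracondylar) and 33C (complete articular) distal femoral fractures, plus
the group-comparison statistics used to contrast the two classes, and a
synthetic phantom cohort with exact ground truth to validate every stage.

## Pipeline stages and their contracts

### Fragments (`label_fragments`, `classify_comminution`)

A case is a `labeled_volume`: an integer voxel grid (0 = background,
≥ 1 = fragment) with mm spacing and origin. When labels are trusted
(`relabel = FALSE`) they are used as given; otherwise fragments are
recomputed as connected components of the nonzero mask, 26-connectivity by
default so that thin oblique fragments do not fall apart into face-disjoint
pieces (6-connectivity is available). Fragment volume is exactly
`voxel count × voxel volume`; a noise floor (default 0.01 cm³) discards
segmentation specks and logs the discarded mass, so volume conservation can
always be audited: before filtering, fragment volumes sum exactly to the
nonzero-voxel volume.

The per-case mean comminuted volume averages comminuted fragments only and
is defined as 0 for cases without comminution. At the cohort level the
class mean is taken over **all** cases of the class with those zeros
included. The published summary table this mirrors does not state which
convention it used; the zeros-included reading is adopted here because it
is the one under which the published pooled-t p-value (0.029) is
reproduced from the printed summaries.

### Reduction and registration (`mirror_model`, `icp_align`, `virtual_reduce`, `spacing_check`)

Right-sided cases are mirrored across the template mid-sagittal plane
(winding flipped, side flag toggled; mirroring twice is the identity).
Registration is point-to-point ICP: nearest-neighbor correspondences
against the template surface sample, Kabsch least-squares update,
terminating when the RMS change drops below 1e-6 mm or after 200
iterations. The RMS is non-increasing across iterations, and the suite
asserts this on every run.

The interactive workflow this automates has a human align the model "in
transparent mode". Here the start pose is chosen as the best of the four
principal-axis alignments (centroids matched; the sign ambiguity of PCA
axes resolved by lowest initial RMS) plus the identity — the identity
matters because models that are already in the template frame should not
be dragged through a worse PCA start.

`virtual_reduce` registers the largest fragment first and uses its
recovered transform as the starting guess for the remaining fragments,
each against the template region near its guess; every fragment must
individually pass the 5 mm gate, and the gate is also applied to the
assembled model (stricter than either alone, since the published method
does not say whether its gate was per fragment or global). After each
fragment converges, a fine-tuning pass nudges the pose by one
surface-sample step (±x, ±y, ±z) and re-runs ICP, keeping strict RMS
improvements: voxelized surfaces produce flat, lattice-aligned local
minima one sample step away from the truth, and this small perturbation
descent reliably escapes them. It is the automated counterpart of the
manual "fine-tune until the distance is acceptable" loop.

A genuine limitation surfaced by the synthetic cohort: a fragment whose
outer surface carries no identifying geometry — a short mid-shaft ring
from a near-cylindrical diaphysis — cannot be localized along the shaft
axis by template registration at all, because every axial slide of its
wall lies exactly on the template wall. The information that would fix it
(the fracture-edge geometry) is not visible to template matching. The
displacement-recovery validation therefore plants transforms on fragments
that include the condylar flare or the shaft end; for featureless rings
the recovered pose is correct only up to axial slide, which still passes
the 5 mm gate and lands lines in the correct region at map scale.

### Mapping (`extract_interface`, `project_to_template`, `accumulate_frequency`)

Interfaces are 6-adjacent voxel pairs with differing nonzero labels —
face adjacency keeps the interface a coherent two-voxel-thick sheet,
where 26-adjacency would inflate it at corners. The fracture line is the
intersection of the interface with the outer boundary (voxels face-
adjacent to background). Projection snaps each mm point to its nearest
template vertex and discards points farther than the cutoff (default
5 mm, matching the gate), counting the discards.

Frequency accumulation is **binary per case per vertex**: however many
line points a case lands on a vertex, it contributes at most 1 to the
count, and the per-case vertex set is first dilated by a Euclidean radius
(default 2 mm) on the vertex cloud — the hand-traced curves of the manual
workflow have finite width, and the published description does not state
it, so the radius is an exposed parameter recorded in the map metadata.
Geodesic dilation was considered and rejected: at a 2 mm radius on a
closed cortical surface the Euclidean and geodesic neighborhoods differ
only at sharp concavities, and the simpler rule is exactly reproducible.
Heat colors are scaled to each map's own maximum (the published captions
describe relative gradients); an absolute scale is available.

Zone extents are measured from the joint-line plane along the superior
axis: the inferior and superior edges of the set of vertices with
frequency strictly above a threshold, restricted to an anatomical sector.
Sectors are defined by the signs of the medial and anterior coordinates
(quadrants/octants about the template axes) — the published zone
descriptions are verbal ("medial column", "anterolateral"), and octants
are the reproducible proxy.

### Statistics (`compare_quantitative`, `compare_categorical`, `t_from_summary`, `cohort_report`)

Quantitative variables follow the decision tree: Shapiro–Wilk on each
group (normal only if both p > α); if normal, Levene's test chooses the
pooled versus Welch t-test; otherwise the Mann–Whitney U test (exact when
both n ≤ 10 without ties, else the tie- and continuity-corrected normal
approximation). Every branch decision is recorded in a `selection_trace`.
Categorical variables use Pearson's chi-square **without** continuity
correction unless more than 20% of cells have expected frequency below 5,
in which case Fisher's exact test is used (two-sided as the sum of table
probabilities no larger than the observed, conditional on margins).

Two conventions are inferred rather than stated in the source material,
and both are verified by the suite against the printed tables:

* *no* continuity correction — the uncorrected statistic reproduces the
  printed 0.059 and 0.574 from the printed counts; the Yates-corrected one
  does not;
* Levene's test uses mean-centered absolute deviations (the classic form;
  the median-centered Brown–Forsythe variant is a different named test).
  It is computed as a one-way ANOVA on the absolute deviations via
  `stats::lm`/`anova`, which is the definition itself.

The normality-gate level equals the significance level (0.05); the source
does not state the gate level separately. No multiple-testing correction
is applied, matching the published analysis. One printed row (the
comminuted-zone fragment count, p = 0.008) is not reproducible from its
printed summaries under any of pooled t, Welch t — the underlying test was
presumably run on raw, non-normal data — so it is excluded from the
reproduction set; the suite reproduces every other printed p-value
exactly at 3-decimal rounding.

## The synthetic phantom and cohort

No patient volumes are distributed with the published study, so validation
runs on a stylized distal-femur phantom with analytic ground truth:

* **Geometry.** A cylindrical shaft (radius 16 mm) flares into two
  superellipsoid condylar lobes (exponent 4) whose x-axes overlap across
  the midline, with a posterior intercondylar notch wedge subtracted.
  Default dimensions are the template's: total length 439 mm, maximum
  condylar width 82 mm. The medial condyle is deeper and extends more
  distally than the lateral one and both sit slightly posterior — enough
  asymmetry that an unmirrored right-sided model fails the 5 mm gate
  while the mirrored one passes, which is what makes the mirroring step
  testable. The template frame puts the joint line at z = 0, +z superior,
  +y anterior, +x medial (left side). The surface mesh is the watertight
  boundary of the voxelization (outward-wound faces), so the mesh volume
  equals the voxel volume identically and the vertex sampling density is
  one point per voxel face — about 1 point/mm² at the default 1 mm
  isotropic spacing, which resolves sub-cm³ fragments with ≥ 500 voxels.

* **Fractures.** Cut surfaces are planes with low-amplitude sinusoidal
  roughness (default 1 mm, wavelength 25 mm) so interfaces are not
  axis-aligned artifacts; an intercondylar split is a near-sagittal cut
  applied only below a z limit, giving the 33C "Y" pattern. Every bone
  voxel receives exactly one fragment label — a strict partition, so
  fragment volumes sum to the phantom volume exactly on every simulated
  case. Comminution-zone fragments are carved inside a planned box by
  seeded distance-ordered region growing: seeds are farthest-point
  sampled, each fragment grows by taking the available region voxels
  closest to its seed, wave by wave, until it holds its target voxel
  count. This differs from a plain Voronoi subdivision deliberately:
  growth hits each volume target to within one voxel (far inside the 10%
  tolerance the generator promises) and guarantees each carved fragment
  is face-connected, which Voronoi cells clipped by the region boundary
  do not.

* **Displacements.** Displacement is off by default — the mapping stage
  consumes reduced (anatomic) models, matching the reduce-then-trace
  order of the method. When enabled, rigid displacements are drawn up to
  10° and 8 mm per non-anchor fragment; published sources do not report
  clinical displacement magnitudes, so these are a modeling choice sized
  to exercise the registration without tearing fragments out of their
  template neighborhood. The label volume always stays in anatomic
  position (it is the partition ground truth); displacements are carried
  on the per-fragment surface point sets and their inverses recorded.

* **Cohort distributions.** Demographics and morphometrics are drawn per
  class from configurable distributions whose defaults emulate the
  published cohort: bimodal age (young high-energy, old low-energy),
  class-specific sex/side/mechanism frequencies taken from the printed
  table, fragment counts from shifted negative binomials matching the
  printed class means (≈ 4 for 33A vs ≈ 8 for 33C), comminution
  probability 33/53 vs 8/21, comminuted fragment volumes log-normal with
  class means ≈ 0.2 vs ≈ 0.7 cm³, and comminution regions placed
  lateral/anterior/posterior for 33A versus anteromedial for 33C. All
  cases are simulated in the left-template frame (side is a recorded
  covariate; mirroring is exercised by its own constructed tests).

What passing on this material shows — and what it does not: the suite
demonstrates that the geometric operators are exact on their contracts
(partition conservation, oracle-equal interfaces, planted-transform
recovery, planted-hotspot recovery within 5 mm) and that the statistical
layer reproduces the published table-derived values. It does not
demonstrate robustness to real segmentation noise, partial volume
effects, osteoporotic cortical thinning, or anatomical variation between
patients and template — the phantom has none of these.

## Numerical choices

* Nearest-neighbor queries run on a uniform hash grid in C++ with a
  deterministic cell size derived from the target cloud's density;
  results are exact (expanding-ring search with a ring lower bound), not
  approximate.
* Voxel→world mapping: voxel (i, j, k), 1-based, sits at
  `origin + (i−1, j−1, k−1) · spacing`; mesh vertices sit on the corner
  grid at half-integer offsets.
* ICP subsamples sources above 5000 points with an even stride;
  termination at RMS change < 1e-6 mm; degenerate (collinear) sources and
  sources under 100 points are rejected.
* The spacing gate is **inclusive** ("within 5 mm" reads as ≤ 5), and
  distances are directional, model → template; the suite pins the gate
  behavior at constructed 0, 5.0 and 6 mm offsets.
* Text outputs format floats at 6 significant digits and every writer is
  deterministic, so identical configurations produce byte-identical
  files; each output embeds the package version and a hash of the
  scientific configuration (paths excluded).
* All randomness flows from a single integer seed through per-case
  derived seeds; RNG state is restored after every simulation call.

## Problem sizes used by the checks

The test suite validates geometry on a 150 × 60 mm phantom at 1 mm
spacing (the full-size 439 × 82 mm template is built once for dimension
and registration checks), runs its end-to-end pipeline at 2 mm spacing
with a 4 + 3 case cohort, and checks hotspot recovery on a 40-case
corridor cohort; statistical behavior under null and planted effects is
measured over 20 seeds at the published 53 + 21 cohort shape. The
acceptance script simulates the full 53 + 21 cohort at the default 1 mm
spacing. These sizes are the package's chosen validation design: large
enough that every contract is exercised at the study's own cohort shape,
small enough to re-run routinely.

## Known limitations

* The phantom is stylized, not anatomical: no anterior bow, no linea
  aspera, no trochlear groove, no cortical/trabecular distinction, and
  no CT grayscale simulation — segmentation is assumed done.
* Axial localization of featureless shaft rings by template ICP is
  fundamentally underdetermined (discussed above).
* Sector definitions are axis-sign octants, not anatomically delineated
  regions.
* DICOM is not read; NIfTI is the only volume carrier. Only ASCII PLY and
  ASCII STL surfaces are supported.
* The partial-articular 33B class is out of scope, as are open/pathological
  fracture morphologies.
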