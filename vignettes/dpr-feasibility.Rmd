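---
title: "Assessing plan reuse in online adaptive radiotherapy with dprfeas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing plan reuse in online adaptive radiotherapy with dprfeas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dprfeas)
```

## The problem

Online adaptive radiotherapy (oART) re-optimizes a treatment plan at every
fraction on an image acquired with the patient set up for treatment. The
dosimetric gain is real, but so is the cost: contouring and re-optimization
keep the patient on the couch for 30–45 minutes. When interfraction motion
is small, a plan generated at an *earlier* fraction may already be
dosimetrically acceptable for today's anatomy. `dprfeas` implements the
retrospective analysis behind that idea for hypofractionated prostate
treatments (36.25 Gy in five fractions on an MR-linac): maintain a
*Dynamic Plan Repository* (DPR) — the offline CT reference plan plus every
online plan generated so far — and ask, at every fraction, which
repository plans would have been acceptable had they been delivered.

Acceptability is judged three ways:

* **Criteria A — clinical goals.** The graded per-structure dose-volume
  constraints used for clinician-independent online workflows
  (optimal / mandatory / marginal / unacceptable tiers). Mandatory bounds
  must hold for every organ at risk at every fraction and for the targets
  in all but at most one fraction; slightly reduced ("marginal") target
  coverage is allowed for a single fraction per course.
* **Criteria B — current clinical practice benchmark (CCPB).** Criteria A
  are strict and not always met in practice. The benchmark recomputes the
  *approved* plan's dose statistics on the verification image of every
  fraction (the anatomy closest to what was actually treated), pools them
  over the cohort, and relaxes each bound to the pooled 25th percentile
  (targets) or 75th percentile (organs at risk) whenever that quartile is
  more permissive than the clinical goal.
* **Criteria C — exceptional circumstances.** When the approved plan
  itself violated Criteria B at a fraction (e.g. extreme intrafraction
  motion), a repository plan is acceptable if it is equivalent or better
  than the approved plan on *every* metric.

By construction the three sets nest: every A-acceptable plan is
B-acceptable, and every B-acceptable plan is C-acceptable.

## The pipeline

For a fraction *n + 1* the repository holds the CT reference plan
(`DPR_0`) and the online plans of fractions 1..*n*. The daily contours are
registered to each repository plan's frame (translation-only, anchored on
the prostate center of mass — online prostate matching is dominated by
translation, and the sources this package models do not state that
rotations were used), rigidly copied "backwards" onto the plan's dose
grid, and the dose-volume metric panel is evaluated on the frozen dose.
Dose is never recomputed: contours move, dose stays, which is what makes
the analysis cheap enough to run for every plan at every fraction. A
complete five-fraction course therefore needs 1+2+3+4+5 = 15 contour
propagations.

The per-fraction benchmark uses the verification anatomy instead: contours
from the verification image are copied onto the approved plan's dose. For
fractions where the verification image showed inadequate coverage and an
adapt-to-position correction was applied, the package models that
correction as a *virtual couch shift* — a rigid translation of the dose
field aligning the planned prostate position with the verification
prostate position. This is a geometric surrogate for segment-aperture
morphing; no claim of equivalence with a re-optimized plan is made, and
density overrides or dose recomputation are out of scope.

Cohort results are aggregated per patient as the number and percentage of
assessable fractions with at least one acceptable repository plan, then
summarized across patients by median, interquartile range
(linear-interpolation quartiles, R type 7), mean, and sample standard
deviation. These conventions reproduce, from the per-patient counts, the
published cohort statistics of the nine-patient study this analysis
mirrors (medians 25/40/60% under A/B/C).

```{r table2}
counts <- data.frame(
  patient = paste0("P", 1:9),
  fractions = c(5, 5, 5, 5, 4, 5, 5, 5, 5),
  n_a = c(2, 1, 0, 2, 1, 1, 3, 2, 1),
  n_b = c(3, 3, 0, 2, 1, 3, 3, 2, 1),
  n_c = c(3, 3, 2, 2, 1, 3, 4, 3, 1))
summarize_cohort(counts)
```

## Decisions where the method description was open

Several numerical conventions are not fixed by the method description;
the package fixes them explicitly:

* **Inclusive bounds.** A value exactly at a bound satisfies it
  (the unacceptable tiers are printed as strict inequalities, consistent
  with inclusive satisfaction of the adjacent tier).
* **V/D metric conventions.** `v_dose` counts voxels with dose
  `>= threshold`; `d_percent` is the exact within-mask voxel-dose order
  statistic (the largest dose received by at least p% of the structure's
  voxels), with no interpolation between voxel values. Both match a
  brute-force enumeration oracle exactly, which is how they are tested.
* **Quartiles.** Linear interpolation between order statistics
  (`quantile(type = 7)`) everywhere — for the benchmark derivation and for
  cohort summaries. This is the convention under which the published
  per-patient counts reproduce the published cohort statistics.
* **Marginal budget accounting.** The once-per-course marginal allowance
  is charged by the *delivered* sequence: repository candidates at
  fraction n are assessed against the budget state left by the approved
  plans of fractions 1..n−1 (`budget_mode = "delivered"`). A
  fresh-budget-per-fraction variant is available
  (`budget_mode = "fresh"`); the conservative delivered-sequence reading
  is the default.
* **Criteria C tolerance.** "Equivalent" is a relative 1e-6 band per
  metric, so floating-point noise cannot flip a dominance decision.
* **Registration.** Translation-only, prostate-anchored; user-supplied
  full rigid transforms are accepted by the geometry layer.
* **Masks vs dose.** Masks are resampled nearest-neighbor (they must stay
  binary) onto the dose grid; dose is only ever moved by the virtual couch
  shift, with trilinear interpolation. The structure-volume denominator of
  relative metrics is the resampled mask's volume.
* **CTV-to-PTV margins.** The clinical margin recipe is configuration,
  defaulting to 5 mm isotropic with 3 mm posterior. This default is a
  package choice typical of MR-guided prostate SBRT, not a value from the
  study protocol (which this package does not have).

## The synthetic cohort

No patient data ships with the package; a seeded generator produces
complete courses with the statistical structure the analysis needs. Each
patient is a parametric pelvic phantom — prostate and seminal vesicles as
ellipsoids, bladder superior-anterior, rectum as a posterior tube, bowel
superior, urethra as a thin axial cylinder — rasterized on a 70×70×70
lattice at 2 mm (the problem size used throughout the package's own
analyses; tests use coarser 3 mm lattices where only structural properties
are at stake). CTVs are unions of the target organs, PTVs come from the
margin recipe above.

**Plan model.** An optimized plan is represented by an analytic conformal
dose: a boost dose (41.5 Gy) throughout the CTV, a smooth shoulder down to
just above the prescription at the PTV surface, and a Gaussian penumbra
(sigma 5 mm, i.e. an 80–20% falloff of ~6 mm, typical of a 7 MV MR-linac
beam) outside. The interior boost is not decorative: the clinical goals
require 40 Gy to cover 90% of the CTV, so a plan flat at the 36.25 Gy
prescription could never satisfy them — real plans for this prescription
carry exactly such a boost. Multiplicative spatially correlated
heterogeneity (SD 1.5%, correlation length 8 mm) emulates the texture of
real optimized dose; without it, every metric collapses onto a handful of
lattice-quantized values and the benchmark quartiles degenerate. With
`dose_noise_sd = 0` the model reduces to the deterministic profile, which
is monotone along outward rays and is what the geometry tests exercise.

**Motion model.** Interfraction motion is a zero-mean Gaussian global
translation (SD 3 mm/axis) plus *residual* translations of the seminal
vesicles, bladder, rectum and bowel relative to the prostate — a
per-patient systematic offset (SD 0.7 × 3 mm) plus a per-fraction random
component (SD 0.5 × 3 mm). The split matters: prostate-anchored
registration cancels any whole-pelvis translation exactly, so without
differential organ motion the repository would be insensitive to motion
amplitude, and without the systematic component the reference plan would
be as good as any online plan — contrary to both clinical experience and
the systematic/random error decomposition standard in radiotherapy.
Bladder/rectum/bowel filling varies as a 10% SD radius jitter.
Intrafraction motion between the daily and verification images is a 1 mm
SD drift (global + residual), with a 10% chance of a 4× excursion — the
occasional large drift that creates the "exceptional circumstances"
Criteria C addresses. One designated patient's prostate swells by 20% in
volume per fraction (isotropic scaling about its center), reproducing the
observed case in which no repository plan ever achieves target coverage.
One designated fraction (patient 5, fraction 5) is marked corrupted and
excluded, giving the study shape of 44 assessable fractions and 130
propagations.

**Calibration.** The generator is calibrated so that at defaults every
patient's reference plan, evaluated on its own anatomy, meets Criteria A —
a consistency requirement, since the analysis presumes approvable plans.
At the defaults above, a nine-patient cohort shows the qualitative
behaviour the analysis is about: a median of ~20% of fractions with an
A-acceptable repository plan, ~80% under the empirically relaxed
benchmark, a benchmark derivation that genuinely relaxes the PTV D98%
bound, rarely-acceptable reference plans, zero acceptability for the
swelling patient, and acceptability that decreases monotonically with
interfraction motion amplitude.

**What the generator does not emulate.** Organ deformation beyond
isotropic swelling and radius jitter; rotations; MR image content (and
hence contouring error — synthetic contours are ground truth, the offline
contour-refinement step of the real workflow has no counterpart here);
beam/segment structure, density overrides, or any dose recomputation.
Passing tests on synthetic cohorts therefore validate the *analysis
machinery* — metrics, grading, benchmark derivation, budget accounting,
aggregation — and the qualitative scenario behaviour, not the clinical
acceptability rates of any real cohort.

## Worked example

```{r study, eval = FALSE}
cfg <- cohort_config(seed = 1)      # nine patients, five fractions
res <- run_study(cfg)
res$summary                         # per-patient counts + cohort statistics
res$criteria_b$changed              # empirically relaxed bounds
res$reference$ct_ref$cohort         # reference-plan-only comparison
```

File-based use mirrors the in-memory API: `write_cohort()` emits NIfTI
volumes plus a JSON manifest, `run_pipeline()` consumes a manifest and
writes `ccpb_stats.csv`, `ccpb_pool.csv`, `daily_vs_verif.csv`,
`criteria_b_derived.json`, `assessments.csv`, per-patient heatmap CSVs,
`table2.csv` and `reference_summary.csv`. `inst/cli/dprfeas` wraps both
as `dprfeas simulate` / `dprfeas run`.

## Numerical notes and limitations

* Distance computations use an exact anisotropic squared Euclidean
  distance transform (Felzenszwalb's lower-envelope algorithm, compiled);
  margin growth is binary dilation with an octant-wise ellipsoidal
  structuring element built from the six directional margins.
* On a 2 mm lattice, nearest-neighbor contour propagation quantizes
  displacements to whole voxels; D98%-type metrics consequently move in
  visible steps. This mirrors what any voxelized retrospective analysis
  does, but exact numerical parity with a commercial treatment planning
  system's interpolation conventions is not claimed anywhere.
* Plan acceptability here is purely constraint-based. Clinical plan
  review weighs dose distributions and patient-specific circumstances
  that no constraint table captures; an "acceptable" repository plan in
  this analysis is a candidate, not a clinical decision.
* Plan ranking when several repository plans are acceptable is out of
  scope; all acceptable plans are reported.
* DICOM-RT import is not provided; the native interchange is NIfTI for
  volumes with JSON manifests for geometry and bookkeeping.
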