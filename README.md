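# dprfeas

Feasibility analysis of treatment-plan reuse in online adaptive
radiotherapy (oART). Online replanning at every fraction is slow and
resource-intensive; when interfraction motion is small, a plan generated
at an earlier fraction may already be dosimetrically acceptable for
today's anatomy. `dprfeas` implements the retrospective analysis of that
idea for hypofractionated prostate treatments (36.25 Gy in five
fractions): maintain a **Dynamic Plan Repository (DPR)** — the offline CT
reference plan plus every online plan generated so far — and determine, at
every fraction, which repository plans would have been acceptable had they
been delivered.

The package is aimed at medical-physics researchers studying oART
workflow efficiency. It provides:

* **Geometry**: regular-grid masks and dose fields, rasterization,
  anisotropic CTV→PTV margin expansion, rigid transforms,
  translation-only prostate-anchored registration (NIfTI + JSON I/O).
* **Dose-volume metrics**: the clinical panel
  V<sub>x Gy</sub> (in cm³ or % of structure) and D<sub>p%</sub> (Gy
  covering the best p% of a structure), computed as exact voxel
  statistics: for a structure S on dose d,
  V<sub>x</sub> = |{v ∈ S : d(v) ≥ x}| and
  D<sub>p%</sub> = max{t : |{v ∈ S : d(v) ≥ t}| ≥ p·|S|/100}.
* **Criteria engine**: graded constraint tables
  (optimal/mandatory/marginal/unacceptable), a once-per-course marginal
  target-coverage budget, and three nested acceptability criteria —
  **A** clinical goals, **B** an empirical current-clinical-practice
  benchmark obtained by relaxing each bound to the pooled verification
  quartile (P25 for targets, P75 for organs at risk) when more
  permissive, and **C** exceptional-circumstance equivalence with the
  approved plan (no worse on every metric when the approved plan itself
  violated B).
* **DPR assessment**: backward propagation of daily contours onto every
  repository plan, per-fraction acceptability matrices, heatmaps, and
  cohort summaries (median/IQR/mean/SD of per-patient acceptable-fraction
  counts and percentages).
* **A seeded synthetic cohort generator** (pelvic phantom, analytic
  conformal dose with boost and Gaussian penumbra, systematic + random
  interfraction motion, organ-filling jitter, intrafraction drift with
  occasional large excursions, progressive prostate swelling, one
  corrupted fraction), so the entire pipeline runs and is tested without
  patient data.

## Worked example

```r
library(dprfeas)

cfg <- cohort_config(seed = 1)   # 9 patients x 5 fractions, study-shaped
res <- run_study(cfg)            # benchmark pass + assessment pass
res$summary
#> <cohort_summary: 9 patients>
#>   Criteria A: N median 1 [1], mean 1.22 [0.97]; % median 20 [20], mean 25 [19]
#>   Criteria B: N median 4 [1], mean 3.11 [1.36]; % median 80 [20], mean 64 [28]
#>   Criteria C: N median 4 [1], mean 3.11 [1.36]; % median 80 [20], mean 64 [28]
#>   fractions: median 5 [IQR 0], mean 4.89 [SD 0.33]
res$criteria_b$changed
#>                 metric old_bound new_bound quartile
#> 1 ptv_psv|d_percent|98     33.71  33.50669 33.50669
res$propagations
#> [1] 130
```

Reading: under the strict clinical goals (A), the median patient could
have reused a repository plan in 20% of fractions; under the empirically
relaxed benchmark (B, here with the PTV D98% bound relaxed from 33.71 Gy
to the pooled 25th percentile 33.51 Gy) the median rises to 80%. The
swelling patient (P3 analog) contributes zero acceptable fractions. The
study layout gives 130 backward contour propagations over 44 assessable
fractions. Reference-plan-only summaries (`res$reference`) show why a
*repository* helps: restricted to the CT reference plan alone the B
median drops to 40%.

Per-patient tables, plan-by-fraction heatmaps and all CSV outputs are
available through `write_cohort()` + `run_pipeline()`, or from the shell
via `inst/cli/dprfeas simulate|run`.

Shipped constraint tables (`inst/extdata/criteria_a.json`,
`criteria_b_study.json`) carry the published clinical goals and the
study's two benchmark relaxations (PTV D98% ≥ 32.38 Gy; rectum
V36Gy ≤ 3.04 cm³).

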