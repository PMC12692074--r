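# lumbalign

Landmark-based morphometry of the sagittal lumbar spine and pelvis, for
researchers asking whether standing-radiograph alignment parameters can
separate acute low back pain (ALBP) patients from asymptomatic controls.

A lateral lumbar radiograph is digitized as 18 named x-y points (posterior
vertebral body corners from the inferior T12 down to the inferior S1, the
anterior T12-inferior and S1-superior corners, the two femoral heads, and
the pubic symphysis). From these the package computes the standard sagittal
alignment battery:

- **Lumbar lordosis** — the Harrison posterior-tangent angles
  (ARA L1-L5, ARA T12-S1: the angle between posterior body tangents of the
  end vertebrae) and the Cobb T12-S1 (inferior T12 endplate vs superior S1
  endplate). Lordosis is negative by convention.
- **Sacral orientation** — sacral base angle SBA (S1 superior endplate to
  horizontal, equal to the sacral slope SS) and PT-S1 (S1 posterior tangent
  to vertical).
- **Pelvic morphology** — the Legaye angle of pelvic incidence
  (API, between the perpendicular to the mid-S1 endplate and the line to
  the hip axis HA, satisfying PI = PT + SS) and the Harrison
  posterior-tangent pelvic incidence angle (PTPIA, between the pelvic
  radius line HA→posterior S1 and the S1 posterior tangent).
- **Elliptical shape of the lordosis** — a least-squares ellipse through
  the 13 posterior corners (direct conic fit polished by orthogonal-distance
  minimization), summarized by the minor-to-major axis ratio **b/a**, where
  *a* is the craniocaudal (chordwise) semi-axis and *b* the sagittal-bulge
  semi-axis.

The statistics module provides the matching group-comparison battery:
per-group descriptives with two-sample t-tests, Spearman correlation
matrices, Cohen's *d* with noncentral-*t* sample-size calculation, and
empirical ROC analysis with the Youden-index cutoff (equal, under the fixed
"higher value predicts ALBP" orientation, to the directional two-sample
Kolmogorov–Smirnov statistic; ties broken toward the largest cutoff).

Because the underlying radiographs are not publicly deposited, the package
ships a seeded synthetic-cohort generator (`spine_from_params()`,
`generate_cohorts()`) that constructs landmark-level subjects whose derived
angles follow specified group distributions, including the bundled
reference distributions of 50 controls and 50 ALBP patients
(`reference_summary()`, `reference_cohort_spec()`).

## Worked example

Fit the lordosis ellipse to 13 exact points on an arc with the
reference-control mean shape:

```r
library(lumbalign)
arc <- sample_arc(0.389, 85, 13, scale = 180)
fit_lordosis_ellipse(arc)
#> Lordosis ellipse fit (direct method)
#>   center (0.0, 0.0) mm; a = 170.2 mm, b = 66.2 mm
#>   b/a = 0.389; rotation -0.0 deg from vertical
#>   arc extent 85.0 deg; rmse 1.43e-13 mm on 13 points
```

Simulate a two-group cohort at the reference distributions (50 subjects per
group, 0.55 mm digitization noise), measure every subject, and run the
analysis battery:

```r
spec <- reference_cohort_spec(n = 50, seed = 1, noise_sd = 0.55)
coh  <- generate_cohorts(spec)
meas <- rbind(measure_cohort(coh$normal), measure_cohort(coh$albp))
run_analyze(meas)
```

The report prints the per-group summary, ROC table, and effect sizes; for
this seed the simulated cohort reproduces the qualitative reference
pattern — both sacral base angle (44.7° vs 39.6°, p = 0.004) and Cobb
T12-S1 (−70.5° vs −65.7°, p = 0.019) larger in magnitude in the ALBP group,
SBA the only reasonable classifier:

```
ROC (value >= cutoff predicts albp):
   variable   auc cutoff sensitivity specificity youden_j
        SBA 0.665   46.5        0.48        0.84     0.32
 Cobb_T12S1 0.387  -58.7        0.18        0.86     0.04
        ...

Effect sizes for significant variables (alpha = 0.05):
  Cobb_T12S1: d = -0.479, required n = 70/group (power 0.80)
  SBA: d = 0.597, required n = 46/group (power 0.80)
```

A sacral base angle above the fitted cutoff flags a forward-rotated sacrum
with hyperlordosis; an AUC near 0.5 (most other variables) means no
discriminative value at this sample size.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/lumbalign.R simulate --out sim --seed 1 --n 50
Rscript inst/cli/lumbalign.R measure  --landmarks sim/landmarks.csv --out meas.csv
Rscript inst/cli/lumbalign.R analyze  --measurements meas.csv --out report
```

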