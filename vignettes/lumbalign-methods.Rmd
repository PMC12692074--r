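---
title: "Sagittal lumbar alignment from digitized landmarks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sagittal lumbar alignment from digitized landmarks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbalign)
```

This vignette documents the models, conventions and numerical choices
behind `lumbalign`: how each radiographic angle is constructed from the 18
digitized landmarks, how the lordosis ellipse is fitted and its b/a ratio
labeled, what the synthetic-cohort generator does and does not emulate, and
how the group-comparison statistics are defined.

## Coordinate frame and landmark model

All coordinates are in mm with x anterior-positive and y superior-positive.
The y axis is taken to be the plumb vertical of the upright film: relative
angles (ARA, Cobb, API, PTPIA) are frame-invariant, while the
gravity-referenced angles (SBA, PT-S1, pelvic tilt) assume this vertical.
The origin is arbitrary.

A complete subject has 18 points: the posterior body corners from the
posterior-inferior T12 corner down to the posterior-inferior S1 corner
(13 points), the anterior-inferior T12 and anterior-superior S1 corners,
the superior aspect of each femoral head, and the pubic symphysis. Subjects
with fewer points are carried as incomplete; each measurement fails (to
`NA` in `measure_all()`) only if a landmark it actually needs is missing.
The pubic symphysis feeds no angle at all.

## Angle constructions

**Posterior tangents.** For L1–L5 and S1 the posterior tangent is the line
through the two digitized posterior corners, oriented cranially. T12 has no
digitized posterior-superior corner, so its tangent is the perpendicular to
the T12 inferior endplate through the posterior-inferior corner. Sagittal
vertebral bodies are close to rectangular, making the perpendicular the
natural surrogate; it is also the only construction available from the
digitized points. This is the one place where the 18-point scheme forces a
modeling choice, and it propagates into ARA T12-S1 only.

**Lordosis.** ARA between two levels is the signed difference of
tangent-to-vertical angles, cranial minus caudal; Cobb T12-S1 is the signed
difference of endplate-to-horizontal slopes (S1 superior minus T12
inferior). Both are negative in lordosis. Two exact identities link the
constructions on noise-free anatomy and are enforced by the test suite:
`|Cobb| = SBA + t12_tilt` (with `t12_tilt` the anterior-superior slope of
the T12 inferior endplate) and `API = PT + SS` (the Legaye relation).

**Pelvic morphology.** The incidence (API) is the unsigned angle at the
S1 mid-endplate between the caudally-oriented endplate normal and the
segment to the hip axis (midpoint of the femoral heads). The normal's
caudal orientation is anchored to the S1 body axis (posterior-superior
minus posterior-inferior corner) rather than "the side the hip axis is on";
the latter silently caps the measurable incidence at 90°, which the random
pelves of the property suite exercise. PTPIA is the unsigned angle between
the pelvic radius line — hip axis to the posterior-superior S1 corner —
and the S1 posterior tangent; on standard anatomy (pelvic radius leaning
posterior, S1 tangent leaning anterior) it decomposes exactly into the
PR-to-vertical lean plus the sacral tilt. The PR endpoint could arguably be
the mid-posterior S1 body instead of its superior corner; the superior
corner is used because it is a digitized point, and the decomposition
identity holds either way.

**Signs in the difference variables.** Lordosis values are negative, so
"API minus lordosis" means the literal subtraction of the printed (signed)
value: 56.8 + (−76.3) = −19.5. SBA and PT-S1 are reported as positive
magnitudes; signedness is carried only inside intermediate computations.

## The lordosis ellipse

The 13 posterior corners are modeled by an ellipse minimizing summed
squared *orthogonal* distances over center, semi-axes and rotation.

- **Seeding.** A direct ellipse-specific conic fit (the numerically stable
  formulation of the constrained algebraic least-squares problem) on
  centroid-centered, radius-normalized points. On noise-free arcs this seed
  is already exact and the polish is skipped (objective below
  `1e-20 × n`).
- **Polish.** BFGS on (center, log-semi-axes, rotation); a Nelder–Mead
  pass runs only if BFGS fails to converge. The orthogonal distance of a
  point is computed by Newton iteration on the foot-point parameter
  (vectorized across points, 40 iterations, `1e-12` step tolerance) with
  two safeguards: non-converged points fall back to a global scan plus
  golden-section refinement, and any "distance" exceeding the distance to
  the Newton starting point (which lies on the ellipse) is recomputed the
  same way — Newton on the foot-point equation can otherwise land on a
  maximizer.
- **Degenerate input.** Points whose second singular value is below
  `1e-8` of the first are rejected as curvature-free before any fit.
- **`grid` method.** A deterministic multi-start over a fixed lattice of
  axis ratios and center offsets, kept as an independent cross-check of the
  direct method (they agree to ~`5e-3` on reference arcs).

**Axis labeling.** The ratio reported is b/a with *a* the craniocaudal
(chordwise) semi-axis and *b* the sagittal-bulge one — a labeling under
which b/a exceeds 1 when the anterior bulge is larger than the chordwise
half-span, as observed clinically. Two rules cover the eccentricity range:
for clearly eccentric fits (axis ratio > 2) *a* is the axis most parallel
to the T12–S1 chord, which is stable even for razor-thin ellipses whose
sharp vertices make parametric angles fragile under noise; for
near-circular fits, where the chord of an apex-ending arc tips diagonally
between the axes, *b* is instead the axis whose vertex lies nearest the
caudal end of the arc (the lordotic apex sits at the sacral end), and the
blunt vertex keeps that choice stable. Whether the original digitizing
program constrained its iteration differently is unknowable from the
published description; the reported observed range (up to 1.5) is only
representable under a labeling of this kind, not under max/min.

`sample_arc()` is the shared oracle: it places n points exactly on an
ellipse of given ratio and angular extent, ending at the bulge vertex,
scaled to a given chord, optionally at prescribed arc-length fractions.
The fit must reproduce the generating ratio to `1e-3` across
`b/a ∈ {0.1, …, 1.2}` at 85° extent, and `1e-6` for a circle.

## The synthetic-cohort generator

The generator inverts the geometry. Its primary parameters per subject are
the sacral base angle, sacral tilt (PT-S1), ellipse ratio and arc extent,
pelvic incidence, and optionally a Cobb target realized through the T12
endplate tilt (`t12_tilt = |Cobb| − SBA`). Construction: the 13 posterior
corners are sampled on the ellipse arc at anatomical arc-length fractions
(alternating ≈10 mm disc and ≈28 mm body spacings along a 180 mm chord),
rotated so the S1 posterior-tangent secant realizes the sacral tilt; the
S1 anterior-superior corner realizes the sacral base angle; the hip axis
is placed on the ray from the S1 mid-endplate realizing the incidence at a
130 mm pelvic radius; femoral heads sit ±7 mm about it and the pubis is a
decorative offset. ARA T12-S1 is therefore emergent,
`−(t12_tilt + sacral_tilt)`, as are ARA L1-L5 and PTPIA from the arc and
pelvis geometry. The noise-free generator→measurement round trip is the
identity on all target angles to `1e-6`°, which is the backbone oracle of
the test suite.

**Cohort draws.** Each specified variable is drawn from a Gaussian
truncated at its specified bounds (the reference presets use the published
per-variable minima and maxima), with correlation imposed by a Gaussian
copula. Two refinements keep the cohort faithful to its nominal moments:

- the underlying (mean, sd) are *moment-matched* so the truncated
  distribution has the requested mean and SD — naive truncation at the
  asymmetric published bounds would, e.g., shift the ALBP Cobb mean by
  about −0.6°;
- draws use antithetic inverse-CDF pairs (u, 1−u), halving-or-better the
  Monte-Carlo error of cohort-level means at moderate n; each marginal
  draw still has the target distribution. Both can be disabled.

Draws yielding unconstructible geometry (a Cobb magnitude at or below the
sacral base angle leaves no admissible T12 tilt) are redrawn; a spec
rejecting more than half of all draws is declared infeasible.

**Digitization noise** is i.i.d. isotropic Gaussian per coordinate. The
default SD of 0.55 mm was calibrated by first-order error propagation so
that the per-angle standard error of repeated digitizations of one subject
lands inside the 1–3° band reported for these measures: the tightest
constraint is ARA L1-L5, whose tangents rest on ≈24 mm posterior body
segments (two tangents ⇒ SEM ≈ √2·√2·0.55/0.024 rad ≈ 2.6°), while the
35 mm endplates give SBA ≈ 1.3°. A 200-replicate Monte-Carlo in the test
suite confirms every angle lies in the band.

**What the generator does not emulate:** real vertebral shape variation
(bodies are reduced to corners), osteophytes or pathology, positioning
error, non-Gaussian marginals, and the full published rank-correlation
structure (the copula preset approximates it after a Spearman→Pearson
conversion and an eigenvalue clip to the nearest positive semi-definite
matrix). Passing tests therefore demonstrate internal consistency of the
pipeline and fidelity to the specified group *distributions*, not that
real radiographs would yield these numbers.

## Statistics

- **Descriptives and t-tests.** Mean/SD/max/min/n per group and a
  two-sided independent t-test per variable; pooled-variance Student by
  default (matching how the reference summaries were compared), Welch as an
  option. Zero variance in both groups flags an undefined t.
- **Spearman correlation** uses tie-corrected ranks with p-values from the
  t-approximation; an exhaustive rank-based oracle checks it on small
  tables. Normality screens (Shapiro–Wilk, and Kolmogorov–Smirnov against
  the fitted normal) are reporting flags only — they justify rank-based
  correlation but never trigger an automatic method switch.
- **Cohen's d** uses the pooled SD; from the bundled reference summaries it
  reproduces 0.617 (SBA) and 0.471 (Cobb T12-S1).
- **Sample size** iterates the exact noncentral-t power of the two-sample
  test (df = 2n−2, noncentrality d√(n/2)) to the smallest n per group
  reaching the target power, via doubling plus binary search; a brute-force
  scan over n ∈ [2, 200] confirms minimality in the tests. For d = 0.471
  this gives 72 per group (the normal approximation would give 71).
- **ROC.** The empirical curve is evaluated at every distinct observed
  value under the *fixed* orientation "value ≥ cutoff predicts ALBP" —
  never auto-flipped, so genuinely anti-discriminative variables report
  AUC < 0.5 rather than being silently inverted. The trapezoidal AUC
  equals the Mann–Whitney U statistic over n₀n₁ with half-credit for ties
  (verified against exhaustive pair counting). The optimal cutoff
  maximizes Youden's J = sensitivity + specificity − 1, which under this
  orientation coincides with the directional two-sample K-S statistic
  max(F₀ − F₁); among tied maxima the largest cutoff is reported, and
  cutoffs are printed to 0.1.

## Problem sizes and reproducibility

The test suite and acceptance script use: 10⁶ draws per group for the
binormal ROC check, 500 noise-free landmark subjects per cohort-fidelity
check, 1 000 random pelves for the pelvic identities, 200 replicates for
the noise band, and arcs of 13 points for every ellipse check — sizes at
which the Monte-Carlo error is comfortably below the tolerance being
asserted. Every stochastic step is seeded; cohort generation is
bit-reproducible from the spec seed, and the CLI refuses to simulate
without one.

## Known limitations

- Segmental (per-disc) rotation angles, coronal-plane measures and disc
  heights are out of scope.
- The T12 tangent surrogate makes ARA T12-S1 exactly
  `−(t12_tilt + PT-S1)` on generated spines; on real spines the posterior
  wall is not exactly perpendicular to the endplate.
- The ellipse fit is unconstrained beyond its axis-ratio bounds check;
  extremely thin true arcs (b/a below ≈0.05) measured under noise can
  return boundary-flagged ratios, mirroring the instability any
  unconstrained conic fit has in that regime.
- The binormal ROC model intentionally ignores the non-normality of the
  real score distributions, so the published optimal cutoff and
  sensitivity/specificity at cutoff are not reproducible from summary
  statistics; only the AUC is.
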