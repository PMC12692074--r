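Package: lumbalign
Title: Sagittal Lumbar Alignment Analysis from Digitized Radiographic Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based morphometry of the sagittal lumbar spine
    and pelvis. Computes the standard alignment angles of a lateral lumbar
    radiograph (posterior-tangent absolute rotation angles, Cobb T12-S1,
    sacral base angle, S1 posterior tangent to vertical, pelvic incidence by
    the Legaye construction and by the posterior-tangent analogue) from
    digitized x-y landmark coordinates, fits a least-squares ellipse to the
    lordotic arc to obtain the b/a axis-ratio shape descriptor, and provides
    the group-comparison statistics used to separate asymptomatic controls
    from acute low back pain patients: descriptives, Spearman correlation,
    Cohen's d, noncentral-t sample-size calculation, and empirical ROC
    analysis with Youden/Kolmogorov-Smirnov cutoff selection. A seeded
    synthetic-cohort generator constructs landmark-level subjects whose
    derived angles follow specified group distributions, so the whole
    pipeline is testable without patient radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
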