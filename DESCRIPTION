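Package: retmorph
Title: Morphometry of the Retinal Microvasculature from Segmented Vessel Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the retinal microvasculature from binary (segmented)
    fundus vessel maps. Estimates per-branch vessel caliber with a Euclidean
    distance transform, splits the vasculature into Thin/Thick/Total caliber
    classes around a dataset-wide mean caliber, and computes 25 morphometric
    traits per class (15 arc/chord and integral-curvature tortuosity measures,
    7 per-scale box-counting fractal ratios, and 3 skeleton junction counts).
    Includes a stochastic branching-tree simulator of vessel maps and aging
    cohorts with ground truth, age-association scans with false-discovery-rate
    control, covariate-adjusted regression, and age-cohort classification with
    Fisher/mRMR/CMIM feature selection, a weighted-neighbor-distance
    classifier, a linear support-vector machine, and participant-grouped
    twofold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    splines,
    png,
    tiff,
    e1071,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
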