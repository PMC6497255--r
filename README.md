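# retmorph

Morphometry of the retinal microvasculature from segmented (binary) vessel
maps, for studies of vascular aging. Given a fundus vessel mask, `retmorph`
estimates per-branch caliber, splits the network into **Thin / Thick /
Total** caliber classes around a dataset-wide mean caliber (the
"uber-mean" Um, threshold `F·Um`, default `F = 0.5`), and scores **25
traits per class — 75 per image**:

- **t1–t15 (tortuosity).** Seven measures per branch — arc/chord ratio
  `T1 = L_c / L_x`, total curvature `T2 = ∫|κ| ds`, total squared curvature
  `T3 = ∫κ² ds`, and their arc- and chord-normalized forms
  `T4 = T2/L_c`, `T5 = T3/L_c`, `T6 = T2/L_x`, `T7 = T3/L_x` — each on the
  sampled anchor contour and on a spline-smoothed contour
  (`t(2k−1)/t(2k)` pairs), plus the smoothed/sampled arc-length ratio t15.
  Curvature comes from central finite differences of the
  arc-length-parametrized centerline.
- **f2–f8 (fractal).** Grid-aligned box counting at box sides 2^s px,
  `f_s = log N_s / log r_s` with `r_s` boxes along the longest side —
  1 for a line, 2 for a plane-filling mask.
- **j1–j3 (junctions).** Skeleton pixels classified by crossing number
  (half the binary transitions around the 8-neighborhood): terminals (j1),
  bifurcations (j2), crossings (j3). Crossings are projection artifacts of
  overlapping vessels and are excluded from association scans by default.

Around the trait engine the package provides the cohort analyses used in
vascular-aging work: Pearson age-association scans with Benjamini–Hochberg
FDR, young/old subgroup summaries, the covariate-adjusted regression
`y = A + A² + A·S + S + x1 + … + x8`, and age-cohort classification (WND
with Fisher scores, linear SVMs on mRMR- and CMIM-selected features,
participant-grouped twofold cross-validation with 10 random splits) — plus
a synthetic vascular-tree and aging-cohort simulator with ground truth, so
the whole pipeline is testable without access to cohort imaging.

## Worked example

```r
library(retmorph)

# a synthetic vessel map with known topology (or load_vessel_map("mask.png"))
g <- grow_vessel_tree(growth_config(seed = 42, p_bif = 0.006))
g$map
#> <vessel_map 'synthetic'> 584 x 565 px, 27820 foreground (non-empty)
g$ground_truth$n_bifurcations
#> [1] 53

res <- extract_traits(g$map)   # caliber split + 75 traits
res$summary
#>   image_id n_branches mean_caliber       um   F n_thick n_thin
#>  synthetic        246     4.221873 4.221873 0.5     229      17
round(res$traits[, c("t1", "t5", "f3", "j1", "j2", "j3")], 3)
#>      t1    t5    f3 j1 j2 j3
#> 1 1.106 1.369 0.969 28  1  0    # Thin
#> 2 1.016 0.277 1.651 40 76 38    # Thick
#> 3 1.015 0.238 1.657 43 86 40    # Total
```

Most branches score Thick (229 of 246), so Thick tracks the Total network;
the Thick-class bifurcation count (j2 = 76) sits near the generator's 53
true forks plus the forks contributed by projection overlaps, which also
show up as the 38 crossings (j3).

An aging cohort, measured and scanned:

```r
sim <- simulate_cohort(cohort_config(n = 60, seed = 1), measure = "total",
                       families = c("tortuosity", "junction"))
pearson_age_scan(sim$cohort, traits = c("j1", "j2", "t1", "t11"))
#>  trait  n      r       p   p_adj
#>     j1 60 -0.551 5.0e-06 0.00002
#>     j2 60 -0.476 1.2e-04 0.00024
#>     t1 60  0.038 7.7e-01 0.77000
#>    t11 60  0.148 2.6e-01 0.35000
```

Terminal and bifurcation counts decline with age (negative r, FDR
significant) — the simulator's default slopes are calibrated so measured j2
falls from about 74 (ages 20–30) to about 31 (over 80) — while the
tortuosity control traits t1 and t11, which carry no programmed age
effect, stay null.

A command-line front end wrapping the same functions lives in
`inst/cli/retmorph.R` (subcommands `extract`, `simulate`, `associate`,
`classify`; every output directory gets a `run_record.json` reproducibility
record).

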