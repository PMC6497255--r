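---
title: "Quantifying the aging retinal microvasculature from segmented vessel maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the aging retinal microvasculature from segmented vessel maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The retinal vasculature is the one capillary bed that can be photographed
non-invasively, and its architecture changes with age: vessels straighten,
branch less, and the network loses complexity. `retmorph` quantifies those
changes from *binary vessel maps* — rasters in which a segmentation program
has already marked vessel pixels — at a working resolution of 565 x 584
pixels (fundus cameras shoot at 3872 x 2592; `downscale_image()` reduces
frames by exact area-weighted averaging through an integral image, a choice
that preserves one- and two-pixel vessels that nearest-neighbour sampling
can delete, and reports the linear factor `sqrt(source_area/target_area)`,
about 5.5 for that format).

Per image the package produces 75 numbers: 25 named traits, each measured on
three caliber classes of the vasculature. This vignette explains the model
behind each trait family, the tunable parameters and their defaults, what
the synthetic cohort generator does and does not emulate, and the numerical
choices a reader would otherwise have to reverse-engineer from the code.

## Caliber classes: Thin, Thick, Total

Vessel caliber is estimated entirely from the mask: at every skeleton pixel,
caliber is twice the Euclidean distance to the nearest background pixel
(`estimate_caliber()`), and a branch's caliber is the mean over its skeleton
pixels. On rendered stripes of known width 3–15 px this estimator is within
1 px of truth (it carries a systematic +0.5 to +1 px because the distance is
measured center-to-center; the tests pin this down).

The *uber-mean* Um is the unweighted mean of per-branch calibers pooled over
all images of a run (`compute_uber_mean()`); branch-level rather than
pixel-level averaging was an open choice and is isolated in one function.
With a factor `F` (default 0.5), each branch is assigned whole to **Thick**
(caliber >= F*Um; ties deliberately go to Thick, since most vessels should
score Thick at the default) or **Thin**, and **Total** is the entire
foreground. Pixel masks for the classes are built by assigning every
foreground pixel to the branch of its nearest skeleton pixel (a labelled
distance transform), with junction pixels following the widest adjacent
branch so class masks stay connected through forks. Traits are then computed
on each class mask independently.

## The 25 traits

**Tortuosity (t1–t15).** Each branch is an ordered pixel sequence between
junctions or endpoints, reduced to *anchor points* at a fixed 4-px arc
spacing before any geometry is measured. The spacing matters: curvature
estimated from every skeleton pixel measures the lattice rather than the
vessel — on identical geometry, per-pixel mean squared curvature varies
several-fold with the rendered vessel width — so anchors are placed just
beyond the lattice correlation length (about the half-width of the thickest
vessels), which removes that artifact while shifting analytic fixtures by
under 0.5%. Seven measures are computed: T1 arc/chord length
ratio; T2 total curvature; T3 total squared curvature; T4, T5 those
integrals per unit arc length; T6, T7 per unit chord length. Curvature is
evaluated by central finite differences of the arc-length-parametrized
coordinates, `kappa = (x'y'' - y'x'')/(x'^2+y'^2)^(3/2)`, at interior
samples, with integration weights that sum exactly to the arc length (the
end cells are absorbed into the first and last interior samples). Every
measure is computed twice: on the *sampled* anchor contour and on a
*smoothed* contour, giving the pairs t1/t2 up to t13/t14; t15 is the
smoothed/sampled arc-length ratio.

The smoothing operator is a least-squares cubic spline of x and y against
arc length with knots every 10 samples, re-sampled at unit arc steps. It
exists because digitized centerlines carry lattice jitter: the thinned
skeleton of a perfectly straight oblique vessel has a sampled arc/chord
ratio of 1.02–1.07, while the smoothed value returns to within 1e-3 of 1
(and for jittered straight lines the smoothed arc is never longer than the
sampled one, so t15 <= 1 there). Analytic fixtures anchor the definitions:
a semicircle of radius 50 gives arc/chord within 2% of pi/2, total curvature
within 2% of pi and total squared curvature within 3% of pi/50. Branches
with fewer than 5 anchors are excluded from tortuosity (finite differences
below ~5 samples are noise), as are branches attached to crossing
clusters, whose centerlines near the overlap are projection geometry
rather than vessel geometry; closed branches (cycles) have no chord, so
their chord-based measures are missing. Per image and class, the
branch values are combined by an unweighted mean per trait — whether the
original implementation averaged, summed or took medians is unknowable from
the text, so the aggregation lives in one function
(`aggregate_tortuosity()`).

**Fractal (f2–f8).** Plain grid-aligned box counting: at scale index s the
box side is 2^s px, N_s is the number of boxes containing foreground, and
the resolution r_s is the number of boxes along the longest image side.
The trait is log(N_s)/log(r_s), which has the analytic limits 1 for a line
and exactly 2 for a filled dyadic square — both asserted against a naive
double-loop box scanner in the tests. Boxes are anchored at the origin with
no grid-offset averaging, which keeps the brute-force oracle exact. Scales
where r_s = 1 are undefined and reported missing.

**Junctions (j1–j3).** Skeleton pixels are classified by crossing number —
half the sum of binary transitions around the 8-neighborhood in cyclic
order: 1 terminal, 2 ridge, 3 fork, >= 4 crossing. j1 counts 8-connected
clusters of terminal pixels. For forks and crossings the package deviates
from naive per-pixel counting: thinning a *thick* fork leaves two
crossing-number-3 pixels up to ~4 px apart, and two vessels overlapping in
projection thin into two separated forks, so counting pixels (or even
adjacent-pixel clusters) double-counts bifurcations by nearly a factor of
two on rendered maps. Instead, junction pixels within a Chebyshev radius
(default 2 px) are merged, and each merged cluster is typed by its
*outgoing branch degree*: 3 attachments is a bifurcation (j2), 4 or more a
crossing (j3). On ideal one-pixel fixtures this reduces to the textbook
rule (a Y counts (j1,j2,j3) = (3,1,0), a + counts (4,0,1)); on rendered
trees it brings measured j2 within ±20% of the generator's true
bifurcation count. j3 remains a projection artifact — distinct vessels
crossing, not true junctions — and is excluded from association scans by
default (`include_j3 = FALSE`).

Empty classes yield 25 missing values, and missing values propagate as
exclusions, never as zeros.

## The synthetic generator

`grow_vessel_tree()` grows a discrete branching random walk: roots fan out
from a disc-like origin on one image border (the optic-nerve-head geometry
of real fundus images — this also keeps the rate of projection crossings
realistic rather than dominated by head-on collisions of unrelated trees);
tips advance in unit steps with Gaussian heading noise (`tau`, rad/step, the
tortuosity dial), bifurcate with per-step probability `p_bif` into two
children deflected by 20–40 degrees with widths from the Murray cubed-sum
rule `w_parent^3 = 2 w_child^3`, and stop at the border, at width < 1 px, or
at `max_steps`. Centerlines are rendered as discs of radius w/2; headings
are rounded to 1e-6 rad before rendering so the lattice is reproducible
across platforms. The generator returns ground truth (true bifurcation and
endpoint counts, per-branch width/arc/chord), which is the oracle for the
topology tests. Defaults — 565 x 584 px, 5 roots, root width 7 px,
`tau = 0.035`, `max_steps = 420` — give images whose uber-mean caliber
(~5 px), Thick-majority split and bifurcation counts sit in the range of
segmented fundus maps.

`simulate_cohort()` draws participant ages uniformly on 20.3–88.4 y, makes
`p_bif` linear in age plus a participant-level random effect (so a
participant's multiple images are correlated, which is what the grouped
cross-validation constraint needs), and generates eight age-correlated
cardiovascular/anthropometric covariates (systolic/diastolic blood
pressure, waist, hip, weight, height, BMI, carotid intima-media thickness)
that are *causally inert given age* — the regression tests rely on that.
The default slopes are calibrated so the measured bifurcation count j2
averages about 74 in the 20–30 y decile and about 31 above 80 y, the
decline reported for the reference cohort; because the j2(p_bif) response
is convex and noisy, the calibration was done against measured decile
means, not against the raw single-tree response (frozen at
`p_bif = 0.0078 - 5.0e-5 * age`, participant sd 8e-4). Heading noise has no
age slope by default, so tortuosity is programmed-null; the arc/chord
ratio t1 is the cleanest control (mean age correlation ~0.02 across
calibration cohorts), with t11 (total curvature per chord length) next
best. The per-length curvature traits all retain a small residual age
coupling (|r| of roughly 0.03–0.06) through branch-length composition and
digitization effects that the bifurcation slope induces — an instructive
property of pixel-level morphometry that the association tests make
visible at n = 300: the t11 control scans clean in most but not all
replicate cohorts.

What the generator does **not** emulate: real segmentation artifacts
(breaks, spurs, missed capillaries), artery/vein identity, optic disc and
macula, field-of-view vignetting, or any nonlinear aging trajectory.
Passing tests therefore demonstrate that the measurement and inference
machinery recovers known structure from controllable inputs — not that the
specific biological effect sizes transfer to any real cohort.

## Statistics

`pearson_age_scan()` correlates each trait with age (one row per
participant — the first image by id, since association analyses use one
image per person), two-sided p-values, Benjamini–Hochberg step-up FDR
across whatever trait set was scanned in the call (the published analyses
adjusted within their reported panels; the family is therefore the
caller's panel, configurable by passing a different `traits` vector).
`young_old_summary()` splits at a cutoff age (default: cohort median) with
shared histogram bins. `regress_trait()` fits
`y = A + A^2 + A:S + S + x1 + ... + x8` by ordinary least squares, errors
on rank-deficient designs naming the collinear columns, and
`regress_scan()` applies FDR per model term across traits.

## Classification

`run_age_classification()` reproduces the three-classifier protocol:
Fisher-score-weighted nearest-neighbor WND (distance exponent -5, the
value used by the WND-CHARM family), and two linear SVMs (C = 1, features
z-normalized by training statistics; the publication names no kernel or
hyperparameters, so the deterministic conservative default is used) on the
top-30 features by mRMR and by CMIM. Mutual information is estimated on 10
equal-frequency bins computed on training data only. Validation is
twofold with 10 randomized splits, randomizing *participants* so that all
images of one person land on one side (asserted on every split), and
per-class training sizes are balanced by downsampling the larger class.
The reported accuracy is the arithmetic mean over (classifier, split,
class) cells — with balanced test classes this coincides with the pooled
frequency of correct calls; with unbalanced ones the macro-average is the
stabler choice and is the one implemented. On null cohorts the aggregate
sits at 1/K within Monte-Carlo error; with the calibrated aging slopes a
young-vs-old contrast (20–37 vs 65–89 y) classifies well above 0.65.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to hold
statistical power while staying lightweight: association recovery uses 20
replicate cohorts of n = 300 (measuring the Total class and the panel
j1, j2, t1, t11, skipping the spline smoothing those traits do not need);
classification calibration uses null cohorts of 56 participants and a
young/old contrast of 120, with all 75 features. Fisher scores cap zero-within-variance features at 1e6; WND
distances are row-rescaled by each test sample's minimum distance before
applying the -5 exponent (argmax-invariant, avoids overflow); exact
duplicates short-circuit to the duplicate's class. Box grids are anchored
at the origin; caliber ties go Thick; curvature at degenerate
(zero-derivative) samples is 0; all random processes take explicit seeds.

## Known limitations

Sampled tortuosity on pixel chains carries lattice bias (use the smoothed
variants when absolute levels matter); the caliber estimator saturates at
+1 px; junction merging at radius 2 can in principle fuse two genuine forks
closer than ~2 px; measured j1 undercounts true endpoints when a tip
terminates inside another vessel's silhouette (a projection effect real
maps share); and the Thin class is empty on sparse synthetic images, in
which case its 25 traits are missing by design.
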