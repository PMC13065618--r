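---
title: "Hydrodynamic profiling of leukocyte-endothelium interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamic profiling of leukocyte-endothelium interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukoflow)
```

## The measurement problem

In a parallel-plate flow chamber, isolated leukocytes are perfused over an
endothelial monolayer while a camera records a single field of view
(600 x 480 um, spatial calibration against a 327 um reference). Cells
captured by adhesion molecules slow from free flow (~10^3 um/s) to rolling
(10-10^2 um/s), show jerky accelerations and decelerations as adhesion
bonds form and break, and may arrest on the endothelium. The classical
read-outs of such assays are three numbers per recording:

* **rolling velocity** -- the mean speed of the first up to 53 consecutive
  cells timed over a fixed 100 um segment of endothelium;
* **rolling flux** -- the number of cells rolling over a defined region of
  interest for more than one minute;
* **adhesion** -- cells remaining essentially stationary for at least 30 s,
  counted in ten randomly placed fields and extrapolated to the 8.77 mm^2
  dish surface.

These three capture broad inflammatory contrasts but little of the
fine-grained dynamics. `leukoflow` additionally computes a panel of **45
hydrodynamic descriptors** per recording from the per-cell velocity and
acceleration series, and feeds them into a stepwise linear discriminant
workflow for classifying clinical phenotypes (here: Healthy, type 1
diabetes, type 2 diabetes, each with and without TNF-alpha activation of
the endothelium).

## From tracks to kinematics

A track is an ordered series of times and calibrated positions. Velocity
is the forward frame difference `v[i] = (x[i+1] - x[i]) / (t[i+1] - t[i])`
and acceleration the forward difference of the velocity series, indexed to
the earlier interval. Only the flow axis (x) enters the descriptors:
transverse motion in a laminar chamber is negligible, and angular or shape
descriptors are deliberately out of scope. Irregular sampling is allowed
(each difference uses its own time step); tracks whose time stamps are not
strictly increasing are **rejected, not re-sorted**, so that tracking
errors surface instead of being masked. A track needs at least three
points to contribute descriptors.

## The 45-descriptor panel

Summaries are computed **per leukocyte first**, then aggregated over the
cell population of a recording. This ordering follows the definitions of
the count variables ("number of leukocytes in each range"), which are
inherently per-cell; the pooled-per-frame alternative is available as the
`pooled` switch of `novel_features()` for sensitivity analysis.

Per cell we form the mean absolute per-frame velocity, the mean signed and
mean absolute acceleration, and the counts of positive/negative rolling
events (frame-to-frame velocity increases/decreases beyond a dead band
`epsilon`, default 0). The population aggregation yields six families:

1. *velocity*: mean and median of the per-cell means, plus per-range means
   over the half-open bins 0-500, 500-1000, 1000-1500, 1500-Inf um/s;
2. *acceleration*: the analogous summaries over the bins
   (-Inf)-(-5000), (-5000)-0, 0-5000, 5000-Inf um/s^2, plus
   velocity/acceleration ratios and products;
3. *rolling*: mean positive and negative event counts and their ratio;
4. *standard deviation*: population SDs (n-1) of the per-cell means and
   derived ratios/products;
5. *interaction products*: all six pairwise products of the four velocity
   range features and all six of the acceleration range features;
6. *counts*: cells per velocity bin and per acceleration bin.

Numerical conventions worth stating explicitly:

* a value exactly on a bin edge belongs to the **upper** bin; the four
  bins cover every finite value;
* cells are binned by mean absolute velocity but by mean **signed**
  acceleration, because the acceleration ranges span negative values;
* acceleration units are um/s^2 throughout (the dimensional consequence of
  differencing a velocity series);
* an empty range contributes feature value 0 while its count distinguishes
  true emptiness -- this keeps the discriminant design matrix complete;
* undefined ratios (zero denominator, SD of a single cell) are `NA`,
  counted, and imputed as 0 with a logged message immediately before any
  discriminant fit.

For the classical adhesion parameter the stationarity radius defaults to
5 um (about one cell radius) and sub-fields default to the full window
(`field_frac = 1`); the rolling-flux region of interest is implemented as
a dwell-overlap count, the stricter of the two readings of "rolling over
an area for more than a minute".

## The synthetic cohort generator

Clinical recordings are not redistributable, so the package ships a seeded
simulator whose output feeds every downstream stage. Cells enter the field
as a Poisson process (`entry_rate`). The motion model is a minimal
three-state chain -- free flow, rolling, arrest -- with per-second
intensities converted to per-frame probabilities by the frame interval:

* capture is decided **at entry** with probability `capture_prob`;
  uncaptured cells transit the window in free flow (at ~1000 um/s they
  cross 600 um in under a second, so a mid-window capture transition would
  be both rare and unidentifiable, and modelling it would also break the
  useful property that degenerate settings -- zero spread, zero jerk, zero
  arrest -- produce exactly constant-velocity tracks);
* rolling cells arrest with intensity `arrest_rate` and are released with
  `release_rate` (rolling <-> arrest);
* while rolling, jerk events occur at `jerk_rate` per second and add a
  velocity step of magnitude `jerk_speed` whose sign alternates from event
  to event, mimicking the make-and-break of adhesion bonds;
* per-frame velocities are Gaussian around the state's mean speed.

The default presets mirror the qualitative clinical contrasts: Healthy
rolls fast (600 um/s) and rarely arrests; T1D rolls slowly (200 um/s) with
frequent jerks; T2D rolls at intermediate speed (400 um/s) but arrests
often; TNF-alpha activation multiplies arrest intensity by 2, slows
rolling by 30%, and raises capture and entry. These are **scenario
parameters, not estimates** -- the source assays report only box-plot-level
contrasts -- and they are deliberately strong: within a group, simulated
individuals differ only by sampling noise, so group separation is much
cleaner than clinical data would be. Passing validation on these cohorts
demonstrates that the analysis chain is correct and calibrated, not that
real patients are this separable.

Biomarker columns are generated per individual (matching a serum assay) by
a Gaussian-copula construction: within each group the named descriptor is
standardized and mixed with independent noise as
`rho * z + sqrt(1 - rho^2) * e`, then rescaled to the requested mean and
SD. The realized within-group correlation converges to `rho` only in
expectation; at n = 10-30 individual draws deviate noticeably.

An optional renderer (`render_and_track()`) closes the video loop: frames
are rasterized as Gaussian blobs plus noise, re-detected as local maxima
(on a padded canvas so blobs entering at the window edge keep a full
neighbourhood), and re-linked by greedy nearest-neighbour association
within a gate. It emulates detection quantization, broken links and
crossing ambiguities -- not phase-contrast optics, pulsatile flow or
endothelial texture.

## Group statistics

Univariate comparisons use one-way ANOVA with Tukey's HSD post hoc test
(studentized-range distribution, harmonic-mean group sizes when cells are
unbalanced -- moot at the balanced n = 10 design). Biomarker-descriptor
association uses pairwise-complete Pearson and Spearman correlations; raw
p-values are reported by default, matching the source workflow's 990
uncorrected comparisons, with a Benjamini-Hochberg switch available.
Covariate adjustment (e.g. age) is out of scope because individual ages
are not modelled.

## Stepwise discriminant analysis

The multivariate engine is written from first principles in the SPSS
idiom. Wilks' lambda is `det(W)/det(T)` over the within-group and total
SSCP matrices. Stepwise selection enters, at each step, the candidate
minimizing the new lambda, provided its partial F-to-enter

$$F = \frac{n - g - q}{g - 1}\left(\frac{\Lambda_q}{\Lambda_{q+1}} - 1\right)$$

reaches `F_in` = 3.84; after each entry any included variable whose
F-to-remove falls below `F_out` = 2.71 leaves. Ties break by column order,
`F_out < F_in` is enforced to prevent cycling, and a minimum **tolerance**
of 0.001 (one minus the within-group squared multiple correlation of a
candidate with the entered set) keeps the selected set numerically well
conditioned -- without it, strongly separated cohorts admit chains of
nearly collinear descriptors whose pooled covariance cannot be inverted.
For two groups and one variable the machinery collapses to the two-sample
t statistic through `lambda = 1 / (1 + t^2/(n-2))`, which the test suite
verifies to 1e-10.

Because descriptor families mix scales spanning ten orders of magnitude
(ratios near 1e-3, range products near 1e8), all rank checks and solves
inside the classifier run on the within-group **correlation** scale and
are mapped back afterwards; the fitted model is mathematically identical
but numerically stable.

Canonical functions come from the eigenstructure of `W^{-1}B`, scaled to
unit pooled within-group variance; standardized coefficients multiply raw
coefficients by the pooled within-group SDs (the SPSS convention --
total-SD standardization is the other defensible reading). Classification
uses Fisher's linear functions with equal priors by default (the design is
balanced); proportional priors are a configuration switch. VIFs are
computed per selected variable by regressing it on its co-predictors.

Leave-one-out validation refits the classification functions on each
fold **with the variable list held fixed**, which mirrors the original
SPSS-style workflow; because selection has seen every observation, these
accuracies are optimistic. An honest nested mode (`nested = TRUE`) re-runs
selection inside every fold and is the right choice when the accuracy
itself is the claim. PCA (correlation matrix, eigenvalue > 1 retention,
normalized varimax by pairwise planar rotations to 1e-6) is exploratory
only.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: a
loop-based re-implementation of the descriptor panel (agreement to 1e-9
relative), determinant-ratio and t-statistic identities for lambda,
`MASS::lda` for classification agreement, `stats::varimax` for rotation,
and textbook sums-of-squares/`ptukey` formulas for the ANOVA stage.
Calibration checks run the stepwise gate on null designs (6 x 10
observations, 10 noise variables; some variable is admitted in roughly 5%
of seeds, the union of ten ~0.45% tails) and on planted designs (a 3 SD
shift among 9 noise variables is recovered, and recovered first, in >= 95%
of seeds). Cohort-level recovery simulates the preset T1D/T2D contrast at
n = 10 per group and requires >= 90% mean LOO accuracy over 20 seeds.

Replicated validation runs use 40-60 s recordings at 0.033-0.05 s frame
intervals -- long enough for 20-40 cells per field, the regime where the
per-cell-then-population aggregation stabilizes -- while single-shot
checks use the full 300 s assay design. The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities at the full
assay design (300 s, 0.033 s frames, n = 10 per group).

## Known limitations

* Identical within-group kinetics make simulated cohorts more separable
  than clinical ones; the near-zero lambdas on preset contrasts are a
  property of the scenario, not a clinical claim.
* The rolling-flux ROI semantics are interpretive (dwell-based); counts
  are near zero for small ROIs unless cells arrest inside them.
* Fixed-list LOO inherits selection optimism by construction; use the
  nested mode for unbiased error estimates.
* The renderer is a geometric emulation; it does not attempt photometric
  realism, and sub-pixel localization is limited to the pixel grid.
* Biomarker generation is linear-Gaussian; heavy-tailed or nonlinear
  biomarker-descriptor relationships are not emulated.
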