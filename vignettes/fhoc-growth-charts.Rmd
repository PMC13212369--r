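---
title: "Measuring the femoral head ossification center and building monotone quantile growth charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the femoral head ossification center and building monotone quantile growth charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhocgrowth)
```

## The problem

The femoral head ossification center (FHOC) is the secondary ossification
nucleus of the capital femoral epiphysis. On an anteroposterior (AP) pelvic
radiograph its size — the maximum transverse diameter, the linear distance
from the medial margin to the outermost lateral point of the ossified head —
tracks hip-joint maturation through childhood and is sensitive to growth
disturbances (developmental dysplasia of the hip, Legg–Calvé–Perthes
disease). Automated pipelines segment the FHOC and then need three
well-specified computational stages, which this package provides:

1. **morphometry** — turn a binary segmentation mask plus its pixel spacing
   into a size in millimetres via two cortical landmarks;
2. **validation statistics** — quantify how well automatic measurements agree
   with a reader's, and how well landmarks and masks match a reference;
3. **growth charts** — convert a measured cohort into age-conditional
   percentile reference curves that are biologically admissible
   (non-decreasing in age, non-crossing across percentiles).

A synthetic-data module generates masks with analytic ground truth and
cohorts with a known age-conditional size distribution, so all of the above
is testable end to end without any radiographs.

## Measurement model

A mask is a binary pixel grid with isotropic spacing (mm/px); coordinates
are 0-based `(row, col)` with pixel centers at integer positions.
Measurement is deliberately simple and fully deterministic:

* **Cleanup**: only the largest 8-connected component is kept
  (`largest_component()`); predicted masks can carry speckle. Area ties are
  broken toward the component containing the lexicographically smallest
  `(row, col)` pixel. An empty mask is a meaningful clinical condition (the
  ossification center has not appeared yet) and raises a dedicated error
  rather than returning zero.
* **Landmarks** (`detect_landmarks()`): the transverse extremes are the
  boundary pixels attaining the minimal and maximal column index. Within an
  extreme column the pixel whose row is closest to the foreground centroid
  row is chosen, ties toward the smaller row. "Medial" vs "lateral" is
  assigned from the hip side (on an AP view the right hip appears image-left).
  We interpret "transverse" as the image-horizontal axis rather than, say,
  the maximum Feret diameter, because the landmark names — medial margin,
  outermost lateral point — are horizontal anatomical extremes on a properly
  positioned AP film.
* **Size** (`measure_size()`): the Euclidean distance between the two
  landmarks times the spacing.

### Discretization accuracy

Against the continuous geometry of a noiseless synthetic shape, each
landmark can be off by up to one column of quantization, so the measured
chord agrees with the analytic chord to within about two pixel spacings for
near-axis-aligned shapes. Two geometric regimes degrade this and are worth
knowing about:

* a strongly tilted, eccentric ellipse: the centroid-row tie-break pulls the
  chosen pixel along the locally flat boundary, shrinking the chord by an
  extra term that grows roughly like $(2\,\Delta r)^2 / (4A)$ pixels, where
  $\Delta r$ is the row offset of the true extreme from the centroid row and
  $A$ the transverse half-extent;
* a crescent cut passing near the widest point of the shape: the boundary's
  column-per-row slope at the cut corner diverges, so no pixel-level rule
  can resolve the continuous corner.

Accordingly, the test fixtures used for *continuous-truth* comparisons are
near-axis-aligned (tilt within a few degrees, cut corners with bounded
slope), mirroring how an FHOC actually lies on a positioned AP radiograph,
while fixtures of arbitrary tilt are validated against an exhaustive
discrete search over boundary pixels, which the detector must match exactly.

## Evaluation metrics

`dice()` is the standard overlap `2|A∩B|/(|A|+|B|)`, defined as 1 when both
masks are empty. `hausdorff()` is the exact (100th percentile) symmetric
Hausdorff distance between boundary point sets — boundaries being foreground
pixels with a background 4-neighbour — scaled to mm. The exact variant was
chosen over HD95 because it has a clean exhaustive oracle; which variant a
given publication reports is often unstated, so comparisons across papers
should be made with care. `radial_errors()` reports the mean radial error
(MRE) and successful detection rates (SDR) at the conventional thresholds
1, 2, 2.5, 3 and 4 mm.

## Agreement statistics

The battery in `agreement_report()` follows standard method-comparison
practice, with differences oriented as *automatic minus reference*:

* **Lin's concordance correlation coefficient** (`ccc()`), computed with
  population (1/n) moments; its confidence interval uses the inverse
  hyperbolic tangent transform with Lin's 1989 asymptotic variance.
* **Pearson r** with the Fisher-z interval `tanh(atanh r ± z/√(n−3))`.
* **MAE / RMSE** with nonparametric case-resampling bootstrap percentile
  intervals (B = 2000 by default, deterministic given a seed). A bootstrap
  was chosen because no distributional form for the errors is assumed
  anywhere else.
* **Bland–Altman** (`bland_altman()`): bias, 95% limits of agreement
  `bias ± 1.96·sd` with the n−1 sample standard deviation and the fixed
  1.96 multiplier (the convention in the radiology literature), the percent
  of pairs inside the limits, and a proportional-bias slope from regressing
  differences on pair means. Note that when one method is noisier than the
  other, this regression has a small negative expected slope even without
  true proportional bias; the planted-effect tests quantify slope recovery
  against that background.
* **Paired t-test** via `stats::t.test(paired = TRUE)`, supplementary to the
  agreement metrics.
* **Fisher Z** (`fisher_z()`) for comparing correlations between independent
  subgroups. When comparing sexes we use the number of hips (rows) as the
  group size; bilateral measurements within a child are correlated, so this
  overstates the effective n somewhat — a caveat inherited from treating
  hips as the unit of analysis.

`stratified_agreement()` applies the battery per stratum (sex, laterality,
twelve age bins 0.5–0.75, 0.75–1, 1–2, …, 10–11 years, or products of
these); strata with fewer than 3 pairs are reported as insufficient rather
than dropped.

## Growth-chart model

`fit_quantile_curves()` fits, per sex and per quantile level
τ ∈ {0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95}, a polynomial in age
minimizing the pinball loss $\sum_i \rho_\tau(y_i - p(a_i))$ subject to
$p'(a) \ge 0$ on a grid of ages (step 0.25 y). Design choices:

* **Degree 3 by default.** The anchored reference median curves are
  approximated by a cubic to within 0.02 mm, and the data (two decades of
  decelerating growth) show no structure a cubic misses; the degree is a
  plain argument for users who disagree.
* **Ages are rescaled to [−1, 1]** internally so the monomial basis is well
  conditioned; coefficients are stored in that basis together with the
  affine map.
* **The constrained problem is a linear program.** It is solved by a
  primal-dual interior-point method written for this package
  (`pinball_fit()`): the LP dual of weighted asymmetric-L1 regression is a
  box-constrained problem whose Newton step costs one (degree+1)² solve, so
  fits with thousands of observations take milliseconds. After convergence
  the solution is *polished* to an exact vertex of the LP by interpolating
  the rows with the smallest residuals (accepted only if it does not worsen
  the objective) — this is what makes an intercept-only fit return an exact
  order statistic, a property the tests rely on.
* **Monotonicity as exact penalty.** The derivative constraints enter the
  same LP as zero-response rows penalized one-sidedly with weight λ; λ is
  escalated (×10, up to three times) until the fitted derivative is
  nonnegative within 1e−7 of the data scale. For a feasible LP a finite λ
  reproduces the constrained solution exactly; if escalation ever fails the
  fit aborts and reports the binding grid ages.
* **Non-crossing by rearrangement.** Fitted quantile curves are sorted
  across levels at every evaluation age. Rearrangement is order-preserving
  and cannot worsen fit; at the sample sizes involved the raw curves rarely
  cross anywhere except deep in the age-domain corners.
* **Hips, not children, are the default observational unit** (two rows per
  child), matching the balanced bilateral design the generator emulates;
  aggregate per child first if you prefer the stricter independence.

`predict_percentiles()` evaluates the rearranged curves and refuses to
extrapolate outside the fitted age domain — a reference chart has no
business reporting values where there were no data. `percentile_of()`
inverts the seven fitted quantiles at a given age by monotone interpolation
and flags sizes outside the 5th–95th band instead of extrapolating.
`adjusted_r2()` is computed from the *median*-curve residuals
(`1 − (1−R²)(n−1)/(n−p−1)`, p = degree); whether a published R² describes
the median curve or a separate mean fit is often unstated, so ours is
labelled explicitly. `group_errors()` reports in-sample MAE/RMSE of the
median curve per age bin with bootstrap intervals; they are in-sample
residual summaries, not held-out prediction errors, and are labelled as
such.

## The synthetic-data generator

The generator defines the study conditions the tests and the acceptance
script run under; it emulates a balanced pediatric radiograph cohort:

* twelve age bins (0.5–0.75 … 10–11 y), ages uniform within bins, both
  sexes, default 25 children per sex per bin (600 children, 1200 hips —
  the scale of a typical held-out validation set);
* per-age size distributions anchored to a per-sex reference table of 5th,
  50th and 95th percentiles at ages 0.5 and 1–11 y (shipped in
  `inst/extdata/`, validated for non-crossing and a non-decreasing median
  at load). Anchors are interpolated by monotone piecewise-cubic splines,
  which cannot introduce spurious dips between table rows;
* the conditional distribution is a **two-piece normal in the quantile
  domain**: a standard normal draw z maps to
  `q50 + z·(q95−q50)/z₀.₉₅` above the median and `q50 + z·(q50−q5)/z₀.₉₅`
  below. We first tried the plainer `Normal(q50, (q95−q5)/(2 z₀.₉₅))`;
  because the anchor table is skewed (q50 is up to 1.4 mm away from the
  q5/q95 midpoint at the oldest ages), that symmetric model cannot
  reproduce the anchored 5th percentile even with unlimited data, so the
  two-piece form — which matches all three anchors exactly and degenerates
  to the symmetric normal when they are symmetric — was adopted. The true
  residual law around a real growth curve is unknown; this is a modelling
  stand-in, not a claim about any particular population;
* left/right hips are drawn from a bivariate normal in z with correlation
  0.98 (bilateral sizes are nearly identical in healthy children),
  truncated to positive sizes by redrawing;
* a simulated reader re-measures with additive bias (default 0) and noise
  (default sd 0.96 mm, chosen so the simulated 95% limits of agreement are
  about ±1.9 mm, the order reported for expert-vs-automatic FHOC
  agreement);
* masks are rasterized ellipses with optional rotation, smooth low-order
  Fourier boundary noise, and an optional inferior "crescent" cut mimicking
  partial ossification; the analytic ground truth (landmark coordinates and
  chord length of the noiseless shape, cut included) is returned alongside.

What the generator does *not* emulate: real radiographic texture,
segmentation failure modes (holes, under-segmentation), pelvic rotation and
tilt, pathology, or any longitudinal correlation within a child across
visits. Tests passing on this generator therefore establish the
correctness of the measurement and statistical machinery under the stated
model — not the clinical performance of any segmentation network.

## Problem sizes and determinism

All randomness flows from explicit integer seeds; a single run seed derives
per-stage seeds by hashing stage names (`derive_seed()`), so any stage can
be re-run in isolation and identical configurations produce identical
tables. The test suite uses cohorts of up to 3000 children per sex for the
anchor-recovery checks (fitted medians within ±0.6 mm of the anchors, 5th
percentiles within ±1.2 mm at every anchored age), 10⁴ pairs for the
Bland–Altman coverage check, 200 replicates of the 1200-hip null reader
simulation, and 200 synthetic masks for the landmark-oracle sweep; the
whole suite runs in well under a minute.

## Known limitations

* The landmark rule reconstructs "extreme-column boundary points with a
  centroid-row tie-break" from the anatomical definition of the
  measurement; a published pipeline's exact post-processing may differ in
  tie-breaking or sub-pixel refinement.
* The exact Hausdorff variant, in-sample group errors, and median-curve R²
  are each one of several conventions in circulation; all are labelled.
* Percentile charts are cross-sectional references, not individual growth
  trajectories; no covariates beyond age and sex are modelled.
* LP vertex polishing assumes the basis rows are numerically well
  conditioned; for pathological designs the interior-point solution is
  returned unpolished (still correct to solver tolerance 1e−7).
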