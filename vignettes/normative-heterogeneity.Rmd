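---
title: "Normative deviation modelling and heterogeneity metrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative deviation modelling and heterogeneity metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normdev)
```

## The problem

Group-average comparisons of brain morphometry hide how differently a disease
expresses itself across individuals. Frontotemporal lobar degeneration (FTLD)
is a canonical example: its clinical variants (bvFTD, svPPA, nfvPPA, CBS,
PSP) differ not only in *where* atrophy concentrates on average but in *how
consistently* individual patients follow the group pattern. `normdev`
implements an individual-deviation analysis of that heterogeneity: each
subject's cortical thickness (148 Destrieux regions) and subcortical volumes
(19 structures) are scored against a normative model of healthy ageing, and
individual-level markers — outlier maps, total outlier counts, within-group
Hamming distances — quantify both the burden and the dissimilarity of atrophy
patterns.

## The normative model

For each region $r$ the healthy reference value $y$ is modelled as

$$y = f_r(\text{age}) + \beta_{r,\text{sex}} \cdot \text{sex} +
      u_{r,\text{site}} + \sigma_{r,\text{site}}\,\varepsilon,$$

where $f_r$ is a cubic B-spline in age (3 interior knots at the reference
age quartiles by default; a raw polynomial is available), site offsets
$u_{r,\text{site}}$ are coded sum-to-zero so the intercept is the across-site
average, the residual scale may differ by site, and $\varepsilon$ is either
standard normal (default) or sinh–arcsinh warped,
$\varepsilon = \sinh((\operatorname{asinh}(z) + \epsilon_w)/\delta_w)$ with
$z \sim N(0,1)$, to accommodate skewed and heavy- or light-tailed residuals.
Estimation is maximum likelihood: the Gaussian heteroscedastic fit alternates
weighted least squares with per-site scale updates (each half-step maximizes
the likelihood in one block, so the recorded log-likelihood trace is
monotone); the warped fit starts from the Gaussian solution and maximizes the
full warped likelihood by BFGS. No random numbers are consumed, so refits are
bit-identical.

This is a deliberate desk-scale stand-in for the hierarchical Bayesian
machinery behind hosted normative-modelling services. Only point deviation
z-scores are consumed downstream, and a maximum-likelihood warped regression
reproduces that contract; posterior sampling and predictive-uncertainty
intervals are out of scope.

### Transfer adaptation

A model fitted on reference scanners does not transfer unchanged to a new
site. `adapt_to_site()` recalibrates it from a local healthy-control set
(by convention an 80% split of the available controls, the remaining 20%
serving as held-out test controls): per region, the adaptation subjects'
residuals under the reference mean function — with unseen-site offsets
marginalized to the reference average — yield a shift (their location, in
measure units) and a scale (their spread relative to the reference residual
scale). The default estimators are the median and the normalized (1.4826×)
MAD because real adaptation sets are small (tens of subjects) and may contain
undetected pathology; mean/sd (`estimator = "moment"`) are selectable and are
the efficient choice when the model is correctly specified and the adaptation
set is comfortably large. Deviation z-scores for test subjects are then

$$z = \frac{y - \hat\mu(\text{age}, \text{sex}, \text{site}) - \widehat{\text{shift}}}
           {\hat\sigma \cdot \widehat{\text{scale}}},$$

passed through the inverse warp when one was fitted. A region whose model the
test data cannot be matched to is an error, never silently dropped.

## Individual heterogeneity markers

* **Outliers.** A region is an outlier when $z < \tau$ with $\tau = -1.96$,
  the 2.5th percentile of the standard normal. The inequality is strict —
  $z = -1.96$ exactly is not an outlier — so boundary behaviour is fixed and
  bit-exact testable. Only negative deviations (atrophy) count by default;
  `two_sided = TRUE` exists as an extension hook.
* **tOC.** The total outlier count is the row sum of the binary matrix per
  region kind: 0–148 for cortical thickness, 0–19 for subcortical volumes.
  The two kinds are always computed and reported separately, never pooled.
* **Hamming distance.** For two subjects of the same diagnostic group, the
  number of regions at which their binary outlier vectors differ, computed
  within one region kind. The implementation uses the identity
  $d(i,j) = \text{tOC}_i + \text{tOC}_j - 2\,(\text{shared outliers})$,
  which the tests verify against a direct position-by-position count.
* **Per-subject median.** Each subject's heterogeneity score is the median of
  its distances to all same-group peers (self excluded, midpoint convention
  for even counts). Group-level comparisons of "median Hamming distance"
  could equally be read as comparisons of the pooled set of pairwise
  distances; the per-subject-median reading is the default and the pooled
  reading is available via `heterogeneity_summary(pooled = TRUE)`. The
  per-subject reading was chosen because it yields one observation per
  subject, keeping the group tests' exchangeability assumptions interpretable
  (pairwise distances are heavily cross-correlated).
* **Proportion maps.** Per region and group, the fraction of members flagged,
  reported with the group size.

## Statistical battery

Demographic and marker comparisons follow a gated design: Shapiro–Wilk per
group at $\alpha = 0.05$ (constant samples are flagged degenerate) routes to
ANOVA/Welch-t on the parametric branch or Kruskal–Wallis/Mann–Whitney on the
nonparametric one. All standard tests call the corresponding `stats::`
implementations; what `normdev` adds is the uniform `stat_result` record,
the effect sizes, and the family definitions:

* Kruskal–Wallis $H$ (tie-corrected) with $\eta^2 = (H - k + 1)/(N - k)$,
  floored at zero. This is the standard $H$-based estimator; it is a design
  choice, not a claim about how any published $\eta^2$ was computed.
* Dunn's post hoc on the pooled ranking with the tie-corrected standard
  error, adjusted across the $k(k-1)/2$ pairs by Bonferroni or
  Benjamini–Hochberg. There is no pre-installed Dunn implementation, so this
  one is written from the mean-rank formula and tested against an
  independent oracle.
* Per-region 2×2 outlier-count screens: Pearson chi-square when all expected
  counts are ≥ 5, otherwise Fisher's exact test (the classical switch;
  the branch taken is recorded per region), BH-adjusted within one region
  kind. Adjustment families are always explicit: Dunn pairs within one
  marker, region screens within one kind, never across kinds.
* Welch t with Satterthwaite df and Cohen's d on the pooled sd; the 95% CI
  inverts the noncentral-t distribution, falling back to the
  normal-approximation CI (recorded in the result) if the inversion fails.
* Mann–Whitney U via the normal approximation with tie-corrected variance
  and 0.5 continuity correction; rank-biserial $r = 2U_1/(n_1 n_2) - 1$ with
  the first sample as reference, so when the mild stratum is passed first a
  "severe worse" result is negative.
* Severity stratification: global score 0.5 → mild, ≥ 1 → severe, 0 or
  missing → excluded with a recorded reason; a merge-zero mode pools 0 with
  0.5 ("≤ 0.5"). The scale used is mapped per diagnosis (CDR for PSP/CBS,
  CDR plus NACC-FTLD for the FTD variants).

## The synthetic cohort generator

Clinical morphometry from multi-site dementia cohorts is access-restricted,
so the generator is a first-class module, not a test fixture. It emulates the
statistical structure the analysis assumes:

* a large multi-site healthy reference (default in `simulate_study_cohort()`:
  4 sites × 250 subjects) with per-site offsets and scales, quadratic age
  curves per decade centred at 65 years, a binary sex effect, and Gaussian or
  sinh–arcsinh noise, on FreeSurfer-like scales (≈2.5 mm thickness with sd
  0.15 mm; thousands of mm³ volumes with sd 350 mm³);
* a local control set (default 63) on held-out target sites, split 80/20 into
  adaptation and test controls;
* five clinical groups at the published group sizes (bvFTD 22, svPPA 21,
  nfvPPA 14, CBS 43, PSP 45) whose subjects start as healthy draws and then
  receive atrophy `depth × noise sd` (times a severity multiplier when the
  global score is ≥ 1) in each signature region independently with the
  group's involvement probability, plus a small off-signature rate. The
  involvement probability is the heterogeneity dial: 1 makes a perfectly
  homogeneous group, lower values raise within-group Hamming distances.
  Signature regions follow the field's descriptions (focal left anterior
  temporal for svPPA, frontal for bvFTD, left inferior frontal for nfvPPA,
  peri-rolandic/parietal for CBS, predominantly subcortical for PSP), and the
  severity distributions echo the published medians (e.g. bvFTD skewed
  toward ≥ 1).

Ages are uniform over the configured range (published cohorts report ranges,
not distributions), sex is a configurable Bernoulli, and one master seed
expands into per-stage child seeds by deterministic hashing so each stage is
individually reproducible. What the generator does **not** emulate: regional
correlation structure within subjects (regions are conditionally independent
given covariates), longitudinal change, segmentation failure, realistic
covariance between age and diagnosis, or site-by-region interactions beyond
a global offset/scale. Passing tests therefore demonstrate that the
machinery is correct under the stated generating model, not that any
particular clinical finding generalizes.

## Numerical choices and degenerate inputs

* Optimizer: WLS/scale alternation stops when the log-likelihood changes by
  less than `tol` (default 1e-8, relative); the warped fit runs BFGS and
  keeps the Gaussian start if a line search ends worse, so traces never
  decrease. Non-convergence warns and flags the region.
* Rank-deficient designs abort with the collinear columns named (a constant
  sex column is the common case); a reference smaller than the design
  dimension plus sites plus two is rejected up front.
* B-spline prediction clamps ages to the reference range rather than
  extrapolating.
* All-tied samples: Kruskal–Wallis returns $H = 0$, $p = 1$; Mann–Whitney
  returns $p = 1$, $r = 0$; Shapiro–Wilk inputs that are constant are routed
  nonparametric with a degenerate flag.
* Regions with no outliers in either group get $p = 1$ and a zero-margin
  flag instead of a test.
* Adaptation requires ≥ 2 subjects (the scale is undefined below that) and a
  strictly positive spread.

## Problem sizes used by the tests

The suite exercises simulations at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: calibration at 5,000–7,500 reference
draws per check, parameter recovery over 100 replicates of n = 500,
the heterogeneity-recovery design at its stated n = 50-per-group over 100
replicates (with one shared normative fit, since the replicated quantity is
the clinical cohort), and the null level of the Kruskal–Wallis test over
2,000 simulations. The calibration acceptance computation follows its stated
recipe exactly: a 5,000-subject two-site reference, 20 regions, adaptation on
200 held-out-site controls, and 10,000 test subjects (200,000 subject-region
draws). At an adaptation size of 200 the per-region shift and scale estimates
carry ~5–7% sampling error that is shared across that region's 10,000 test
subjects; this, not the binomial noise of the draws, dominates the spread of
the flagged fraction around 2.5% and slightly biases it upward (the tail
probability is convex in the scale error). The moment estimators are used
there because the scenario is correctly specified Gaussian.

## Known limitations

* The normative engine is a point-estimate ML model: no posterior weights,
  no epistemic uncertainty on the z-scores.
* The warp recalibration applies the adaptation shift/scale on the raw
  residual before the inverse warp; if the target site's residual *shape*
  (not just location/scale) differs from the reference, calibration is
  approximate.
* Visual quality control cannot be encoded; the pipeline only honours
  precomputed exclusions upstream of its inputs.
* Region definitions are taken as given; no surface rendering or atlas
  manipulation is provided.
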