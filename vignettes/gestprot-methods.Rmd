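---
title: "Methods: longitudinal plasma proteomics of fetal growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal plasma proteomics of fetal growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Maternal plasma protein abundance changes smoothly and substantially across
gestation, and any comparison between pregnancies sampled at slightly
different gestational ages confounds biology with sampling time. This
package implements a longitudinal proteomics workflow for cohorts in which
each participant is sampled at three visits (gestational windows 12–19,
21–27 and 28–34 weeks) and newborns are classified by birth-weight z-score:
small for gestational age (SGA, z < −1.3), large for gestational age (LGA,
z > 1.3) and adequate (AGA, in between, boundaries inclusive). The cohort
design the package emulates has 7 SGA, 58 AGA and 5 LGA participants —
heavily imbalanced, as population percentile cutoffs imply.

The workflow has five stages, each exposed as ordinary functions:

1. **Preprocessing to MoM values** (`winsorize`, `log2_transform`,
   `fit_reference_curves`, `compute_mom`, `preprocess_cohort`). Per protein,
   raw relative-fluorescence values above twice the 98th percentile are
   clipped to exactly that threshold; values are log2-transformed; a
   penalized cubic regression spline of log2 abundance on gestational age is
   fitted to the AGA samples only, with basis dimension k chosen among
   {3, 4, 5, 6} by highest r²; and every sample's MoM value is its log2
   abundance minus the fitted reference value at its gestational age. MoM
   values are deviations from the gestational-age-expected abundance, so
   samples from different visits become comparable.
2. **Clinical comparisons** (`welch_t`, `fisher_exact_rxc`,
   `spearman_corr`, `clinical_summary_table`): Welch's unequal-variance t
   for continuous variables (also directly from published summary
   statistics), Fisher's exact test for 2×2 and 2×3 tables by full
   enumeration, Spearman correlation with the t-approximation p-value.
3. **Moderated differential testing** (`differential_abundance`,
   `associate_with_zscore`). Per protein and visit, ordinary least squares
   of MoM on a case indicator (LGA–AGA or SGA–AGA on the two-group subset)
   or on the birth-weight z-score, adjusted for BMI and nulliparity;
   residual variances are shrunk toward an empirical-Bayes prior and
   moderated t-statistics tested on `d0 + d` degrees of freedom;
   Benjamini–Hochberg q-values with significance at q < 0.05.
4. **Cross-validated prediction** (`loo_cv_predict`,
   `evaluate_predictions`). Leave-one-out CV of a binary LGA-vs-AGA or
   SGA-vs-AGA classifier (elastic net or random forest), with moderated-t
   feature screening repeated inside every training fold, and
   imbalance-aware evaluation (ROC-AUC with DeLong interval, PR-AUC, F1,
   balanced accuracy).
5. **Over-representation analysis** (`run_ora`, `simplify_terms`,
   `cluster_terms`). Hypergeometric enrichment of a hit list against GMT
   gene sets with BH-FDR, retention at q < 0.2 with at least three
   overlapping proteins, greedy Jaccard redundancy reduction, and
   average-linkage clustering of terms on 1 − Jaccard.

# The empirical-Bayes moderation model

For protein $g$, OLS gives $\hat\beta_g$ with unscaled variance $v$,
residual variance $s_g^2$ on $d$ degrees of freedom. The hierarchical model
is

$$ s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d, \qquad
   \sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}, $$

and the prior $(d_0, s_0^2)$ is fitted by matching the mean and variance of
$\log s_g^2$ across proteins to their digamma/trigamma expressions, the
trigamma equation being inverted by a monotone Newton iteration. The
posterior variance is the degrees-of-freedom-weighted combination
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, and the moderated
statistic $t_g = \hat\beta_g / (\tilde s_g \sqrt{v})$ is referred to a t
distribution on $d_0 + d$ degrees of freedom. When the observed variances
show no excess dispersion over the $\chi^2_d$ expectation, $d_0 = \infty$
and every protein is assigned the common prior variance; when $d_0 = 0$ the
statistic reduces exactly to the classical t — both limits are tested. The
moderation machinery is implemented in the package from the moment-matching
formulation; the test suite cross-checks it against the independent
implementation in `limma` on a shared fixture.

# The synthetic cohort generator

No public data accompany this design, so the package ships a first-class
generator (`cohort_config`, `generate_cohort`) that produces a sample
table, an RFU matrix and a ground-truth record. The generative model:

* log2 abundance = protein baseline + smooth gestational trend +
  participant random intercept + group effect (flagged proteins only) +
  Gaussian noise; RFU = 2^log2.
* Trends are per-protein quadratics on a scaled gestational-age axis plus
  an optional small sinusoid — smooth, nonlinear and recoverable by the
  spline engine.
* Birth-weight z-scores are drawn from group-conditional normals
  *truncated to the group's defining interval*, so the group label is
  always consistent with the z-score — an invariant the readers enforce.
* Gestational ages come from per-visit truncated normals inside the visit
  windows.
* Heavy-tailed outliers are emulated by multiplying a small random
  fraction of entries by a large factor (`inject_outliers`).

Defaults mirror the emulated study design: 7/58/5 participants; visit
gestational-age means (SD) 15.7 (1.2), 23.4 (1.0), 31.3 (0.97) weeks;
z-score means (SD) of −1.9 (0.35), −0.12 (0.58) and 1.7 (0.30) for
SGA/AGA/LGA; BMI ~ N(24.1, 2.8²); nulliparity probability 0.5. Defaults
chosen by this package where the design gives no value: 500 proteins (a
desk-scale stand-in for the several thousand an aptamer panel measures,
with full scale available by configuration); 16 LGA-affected and 4
SGA-affected proteins (preserving the affected fraction and the small
absolute SGA count of the emulated study); a constant +0.5 log2 group
effect (positive, matching the observation that all LGA-differential
proteins were elevated; a per-visit effect vector is a configuration
switch); random-intercept SD 0.3 and residual SD 0.25 log2 units; outlier
rate 0.002 with factor 8. The generator does **not** emulate aptamer
cross-reactivity, plate effects, limit-of-detection censoring or
covariate–group confounding (the latter can be introduced manually), so
green tests certify the statistical machinery, not robustness to those
artifacts.

# Numerical and design choices

* **Quantiles** use linear interpolation between order statistics (R type
  7); winsorization thresholds are computed per protein pooled across all
  samples and visits, on pre-clipping values.
* **Spline engine**: the reference curves and the per-group trajectory
  fits share one engine built on penalized B-spline (P-spline) smooths
  (`mgcv::gam`, basis `"ps"` with a difference penalty, GCV smoothness
  selection; cubic B-splines for k ≥ 4, quadratic at the minimal k = 3).
  Unlike natural-spline bases, the B-spline basis spans low-order
  polynomials, so noiseless linear and quadratic signals are recovered
  exactly — a property the tests rely on. k is selected
  by plain r² = 1 − RSS/TSS on the training points, ties toward smaller k
  and r² defined as 0 for a constant response. Fewer than k_max + 2
  distinct reference ages triggers a least-squares-line fallback with a
  warning. Outside the reference gestational-age range the curve continues
  linearly with the boundary slope, giving bounded extrapolation for SGA
  and LGA samples at extreme gestational ages.
* **Fisher's exact test** enumerates all 2×C tables (C ≤ 3) with the
  observed margins and sums probabilities ≤ observed × (1 + 1e−7); that
  relative tolerance is what reproduces published two-decimal p-values on
  knife-edge ties. Boundary z-scores of exactly ±1.3 classify as AGA
  (strict inequalities).
* **Per-visit pairwise models**: each contrast is fitted on the two-group
  subset at one visit (no pooled three-group variance beyond the EB prior,
  no longitudinal mixed model), matching the per-visit volcano-style
  analysis this workflow supports.
* **Nested tuning**: elastic-net hyperparameters are tuned by stratified
  5-fold CV *inside* each LOO training fold over a 10 × 10 grid (α equally
  spaced on [0, 1]; λ log-spaced on [1e−3, 1e1] after within-fold
  standardization), maximizing inner ROC-AUC. Nesting is the only reading
  of LOO-CV plus tuning that cannot leak the held-out sample. Random
  forests use 500 trees and ⌊√p⌋ features per split on raw MoM values.
  Per-fold RNG is derived deterministically from the master seed and fold
  index, making every CV run bit-reproducible.
* **Metrics**: ROC-AUC by the Mann–Whitney mid-rank formulation; its
  confidence interval by the DeLong placement-value variance (default
  level 0.95, configurable, e.g. 0.98); PR-AUC by interpolation-free step
  summation; F1 and balanced accuracy at threshold 0.5 with the minority
  class positive. A reported balanced accuracy of 0 is impossible under
  this standard definition whenever ranking performance is good; the
  package implements the standard definition.
* **ORA**: the background is the user's full measured-protein list; BH is
  applied across the sets actually testable after background intersection.
  The `simplify_terms` redundancy filter is a greedy set-based Jaccard
  rule (keep by ascending p unless similarity ≥ cutoff, default 0.7,
  with any already-kept term) — deliberately simpler than
  ontology-topology-aware "simplify" procedures, and documented as such.

# Problem sizes in the shipped tests

The test suite and the acceptance script run the full pipeline at reduced
but statistically meaningful scale, chosen once as what a desk-scale
simulation study in this field would use: cohorts of 70 participants with
100–500 proteins, 100-seed Monte-Carlo loops for unbiasedness checks,
200 simulated datasets for FDR control, 20 seeds for the permutation-null
and leakage checks of the CV machinery, and a 19-permutation null
distribution for the imbalanced-signal property. The published cohort's
headline counts (148 LGA-differential proteins among 4565, prediction AUCs
near 0.85) arise from an inaccessible dataset; the suite therefore tests
properties — calibration, unbiasedness, leakage-freedom, FDR control —
rather than those numbers.

# Known limitations

* MoM detrending removes gestational-age structure but not
  participant-level abundance shifts (the generator's random intercepts,
  or global sample effects in real data). With very few cases, a chance
  alignment of such shifts moves *all* proteins in the same direction at
  once, so per-contrast discovery counts are strongly correlated across
  proteins and volatile across cohorts — most visibly for the 7-case SGA
  contrast. The moderated tests remain marginally calibrated per protein;
  it is the joint behavior that is heavy-tailed.

* The reference-curve engine presumes enough AGA samples per protein to
  support a spline; very small reference groups silently degrade to a
  straight line (with a warning), which can leave curvature in MoM values.
* The SGA-vs-AGA contrast at 7 cases has little power; the package
  reports honest q-values rather than attempting to rescue power.
* Elastic-net tuning at LOO scale refits the grid for every fold; at full
  aptamer-panel scale (thousands of proteins, `n_features = "all"`) this
  is computationally heavy, and screening to ≤ 50 proteins is the
  supported fast path.
* The generator's group effects are constant in gestational age by
  default; visit-specific effect patterns must be configured explicitly.
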