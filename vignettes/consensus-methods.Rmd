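---
title: "Consensus biomarker selection for case-control plasma metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus biomarker selection for case-control plasma metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Untargeted LC-HRMS metabolomics of a case-control cohort produces a matrix
of feature intensities (here: plasma metabolites for glaucoma patients
versus age- and sex-matched controls) contaminated by instrumental drift,
unreliable features, and far more variables than samples. No single
feature-selection strategy is trustworthy on its own: filter methods
(univariate tests with thresholds) ignore multivariate structure, wrapper
methods overfit, and embedded methods (penalised models) are unstable at
small n. `metaboconsensus` implements the synergistic alternative: run four
complementary branches — univariate filtering, OPLS-DA projection, a
bootstrapped multi-classifier wrapper, and resampled-LASSO stability
selection — and report the consensus of their selections as the final
signature.

# Data model and preprocessing

A cohort is a `MetaboExperiment` (a `SummarizedExperiment`): one intensity
assay (features x samples), per-sample role (`case`, `control`, `qc`,
`dilution`), injection order, and dilution factor. Pooled-QC samples are
repeated injections of one pool; the dilution triple measures the pool at
relative concentrations 1, 1/2 and 1/4.

Preprocessing has four steps, each with an explicit contract:

* **Drift correction** (`correctDrift`): per feature, a LOESS curve
  (span 0.75, degree 1 — the common default of QC-based normalisation
  workflows; the span is exposed) is fit to QC intensity versus injection
  order, and every sample is divided by the fitted value at its own order,
  re-anchored to the QC median so units are preserved. Degree 1 guarantees
  that a purely linear drift is removed exactly. Features whose fit is
  non-positive anywhere are flagged and passed through.
* **Quality filters** (`filterFeatures`): QC coefficient of variation
  strictly below 0.30; dilution-series OLS r² of intensity versus dilution
  factor at least 0.8 (inclusive); no missing values in any sample. The
  strict/inclusive asymmetry is deliberate and matches the wording of the
  thresholds ("below 30%" versus "r² ≥ 0.8"). Filters are independent
  predicates, so their order is irrelevant. They run on **pre-correction**
  intensities by default (`filter_post_loess = FALSE`): the CV filter is
  meant to measure raw analytical repeatability, and the post-LOESS QC
  residuals are deflated by construction (the curve is fit to the very
  injections the CV is computed from); the dilution triple additionally
  sits beyond the last QC where the LOESS extrapolates.
* **Transformation** (`logParetoTransform`): natural log (base
  configurable), then Pareto scaling — centre and divide by the square root
  of the log-scale standard deviation. Pareto scaling leaves each column
  with variance equal to its log-sd, a compromise between no scaling and
  unit variance that damps the dominance of high-variance features without
  amplifying noise floor features. Only study samples enter the
  statistical matrix. Zero/negative intensities are an error; zero-variance
  features are dropped with a warning.

Fold changes are computed on drift-corrected **raw** intensities (ratios on
the log/Pareto scale would be meaningless), as the ratio of case to control
medians; the "effective" fold change `max(FC, 1/FC)` folds decreases onto
the same scale as increases.

# The four branches

**Univariate** (`univariateStats`, `selectUnivariate`): two-sided Wilcoxon
rank-sum per feature (exact enumeration when the data are tie-free and the
combined n is at most 30, tie-corrected normal approximation with
continuity correction otherwise), Benjamini-Hochberg step-up adjustment,
then the two strict gates q < 0.05 and effective FC > 1.5.

**OPLS-DA** (`fitOplsda` and friends): one predictive latent component plus
`nOrth` orthogonal components (default 1) extracted by NIPALS-style
orthogonal signal correction on the centred matrix with the class coded ±1.
Diagnostics: R²Y; Q² from stratified 7-fold cross-validation
(1 − PRESS/SSY); a CV-ANOVA F-test comparing cross-validated residuals to
residuals about the class-code mean with one degree of freedom per fitted
component; a label-permutation test reporting the intercepts of R²Y and Q²
regressed on the permuted-to-true label correlation; VIP (predictive
component, so mean(VIP²) = 1 exactly); and the S-plot coordinates
p1 = cov(t, x_j), p(corr)1 = cor(t, x_j) (defined as 0 for zero-variance
columns). Feature selection combines three reliability criteria:

1. VIP strictly above 1.3;
2. |p(corr)| ≥ 0.4, the customary S-plot influence cut-off — without it,
   VIP alone admits features whose within-dataset correlation with the
   class is indistinguishable from the extreme order statistics of pure
   noise at n ≈ 64;
3. a jack-knife confidence interval on the loading, across the
   cross-validation rounds, that excludes zero. The variance estimate is
   the delete-d jackknife `(g−1)/g · Σ(θᵢ − θ̄)²`: the g leave-group-out
   refits share most of their samples, so the naive `sd/√g` of the fold
   estimates would understate the uncertainty roughly six-fold at g = 7.

**Wrapper selection** (`biosignerSelect`): for each of three classifiers —
single-component PLS-DA, random forest (Gini importance), linear SVM
(|weight| importance) — features are ranked by importance averaged over
stratified bootstraps, and a binary search over the ranked list finds the
smallest prefix whose out-of-bag balanced accuracy beats the accuracy
obtained after permuting those features' values within the out-of-bag
samples. Significance is a paired draw-level permutation p-value,
`(1 + #{perm ≥ obs}) / (1 + nBoot)`: the bootstraps all share one dataset,
so pooling them as independent evidence (a sign or binomial test) would
let small dataset-level chance patterns reach significance on pure-noise
data; the draw-level form compares the effect against per-resampling
variability and restores calibration. The search iterates until the subset
stops shrinking; the fixed point is the classifier's S tier (empty when
even the full set cannot beat its permuted self). Balanced accuracy is
used throughout because the class sizes differ. Only the S tier is
reported (the restricted mode); the consensus layer unions the
per-classifier tiers.

**Stability selection** (`runStabilitySelection`): 1000 stratified
~2/3 / ~1/3 train/test splits (200 in the packaged benchmarks — see below);
per split an L1-penalised logistic regression is fit on the training set,
with the penalty chosen by internal cross-validation on the training set
only (`lambda.1se` by default for sparser, stabler supports; `lambda.min`
is exposed), and scored on the test set by AUC. If the median test AUC is
below 0.8 the whole selection is marked invalid and downstream use is an
error. Over the "excellent" models (test AUC ≥ 0.9) each feature gets its
selection frequency F and median coefficient C (zeros included, so never-
selected features sit at C = 0 — the vertical branch of the Y-plot).
Groups: I if F ≥ (250/303)·n_excellent, II if F ≥ (100/303)·n_excellent,
III otherwise; the thresholds are fractions of the excellent-model count so
the procedure scales with the number of splits. The final LASSO-branch
selection intersects group I with VIP ≥ 1.3 (inclusive, matching the
wording "less than 1.3" for the excluded features) and q < 0.05. One child
seed is spawned per split; the glmnet convergence threshold is tightened to
1e-10 so the selected support does not depend on the column order the
coordinate-descent iterates follow.

**Consensus** (`buildConsensus`): per-feature method flags, Venn counts
over non-empty method subsets, and the signature under a configurable rule.
The default `union-univ-oplsda` — the union of the univariate and OPLS-DA
selections — is the rule that reproduces the published nine-metabolite
signature from the packaged selection table: the wrapper and LASSO branches
select subsets of it, and one high-fold-change metabolite (cystathionine)
enters through the univariate branch alone. `any-2` and `all-flagged` are
provided as stricter/looser alternatives. Ordering is by supporting-method
count, then q-value.

# The synthetic cohort generator

`generateCohort` emulates the study conditions so the whole pipeline is
testable without instrument data: 34 cases vs 30 controls, 160 quality
features of which nine carry the published signature fold changes
(0.469–1.846, i.e. effective fold changes 1.31–2.13), 40 junk features, 10
pooled-QC injections spread across the run, one dilution triple, and a
smooth ±10% drift (the drift magnitude is not constrained by any published
value; ±10% is a realistic single-batch excursion).

Intensities are lognormal around a feature median — multiplicative noise is
what the CV filter and the log transform presuppose — with the case median
equal to the control median times the planted fold change, so at zero noise
the median-ratio fold change is reproduced exactly. Study samples carry 25%
total (biological + analytical) CV; QC and dilution injections carry 10%
analytical CV, reflecting that repeated injections of one pool vary far
less than samples from different subjects. Junk features cycle through
three failure modes: analytical CV drawn from 0.8–1.5 (fails the CV
filter), missing values (fails completeness), and a tent-shaped saturated
dilution response whose OLS r² is ~0.04 by construction — a flat response
was rejected because with only three dilution points its r² under noise is
approximately Beta(1/2, 1/2) and would pass the 0.8 threshold about 30% of
the time. The RNG stream is consumed feature-parameters first, then sample
values, so enlarging a cohort does not reshuffle feature parameters, and a
seed fully determines the table.

What the generator does **not** emulate: feature-feature correlation
(metabolites in shared pathways co-vary; all simulated features are
independent given the class), age/sex confounding, retention-time/mass
structure, missingness in quality features, and multi-batch effects.
Passing the packaged benchmarks therefore shows the machinery is correct
and calibrated under the stated noise model, not that the pipeline's error
rates transfer to any particular real cohort — with correlated features
the OPLS-DA false-positive gates and the LASSO support stability both
degrade.

# Benchmarks and problem sizes

The test suite and the acceptance script rerun the pipeline at the study
scale (64 study samples, 200 candidate features): 50 seeded cohorts for the
recovery benchmarks of the univariate and OPLS-DA branches (target: at
least 7 of the 9 planted features with at most 2 false positives in at
least 80% of seeds), one 200-split stability selection (the two strongest
planted effects must reach group I), a 100-split null-cohort stability run
(gate must fire, median AUC near 0.5), and 50 null cohorts for the wrapper
(S tiers empty in at least 90%). Unit tests use smaller cohorts where the
property under test does not depend on cohort size. The univariate branch's
recovery is assessed at its FDR gate (q < 0.05): the planted panel
deliberately includes three effects whose true effective fold change is
below 1.5, so the full univariate signature rule cannot recover more than
six of nine by design — exactly as in the published table, where the
28-metabolite FDR list narrows to six by the fold-change gate.

# Known limitations

* Single-batch design: no between-batch anchoring of the LOESS correction.
* The CV-ANOVA degrees of freedom are an approximation (one per fitted
  latent component); its p-values are indicative rather than exact.
* The wrapper's binary search assumes the significance of a prefix is
  monotone in its length, which resampling noise can violate; with 50
  bootstraps the smallest attainable p-value is 1/51, so thresholds below
  0.02 require more bootstraps.
* Exact Wilcoxon p-values require tie-free data; intensities that have
  been rounded upstream will silently use the normal approximation.
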