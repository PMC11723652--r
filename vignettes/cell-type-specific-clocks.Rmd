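---
title: "Cell-type specific epigenetic clocks: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type specific epigenetic clocks: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mixture model of bulk DNA methylation

A bulk-tissue methylome is a convex combination of cell-type methylomes.
Writing `f_ts` for the fraction of cell type `t` in sample `s` and
`beta_cts` for the methylation of CpG `c` in that cell type,

    beta_cs = sum_t f_ts * beta_cts + eps_cs.

Chronological age can enter this expression through two routes: the
within-cell-type profiles `beta_cts` can drift with age (intrinsic
aging), and the fractions `f_ts` themselves can shift with age
(extrinsic aging — in blood, for example, lymphocyte subsets change with
age). Any age predictor trained on bulk data absorbs both sources, which
matters whenever the scientific question is about cell-autonomous aging
or when a disease alters tissue composition and thereby confounds "age
acceleration". Everything in this package exists to make that
distinction explicit.

## Fraction estimation

`estimate_fractions()` regresses each sample's betas at the reference
marker CpGs on the reference profiles. There is no intercept: the
reference columns span the expected signal, and an intercept would
absorb fraction mass. Negative coefficients are truncated to zero and
the result renormalized, so every output row is a point on the cell-type
simplex (this truncate-then-renormalize rule is standard practice in
reference-based DNAm deconvolution and is what the simplex invariant
requires). Two solvers are provided: `"robust"`, an iteratively
reweighted least squares with Huber loss (tuning constant 1.345, MAD
residual scale), mimicking the robust behaviour of the widely used
deconvolution tools; and `"nnls"`, exact non-negative least squares,
which is deterministic and serves as the oracle in tests. On noiseless
mixtures the two agree to well below 0.01.

## The interaction model for age-DMCTs

`fit_celldmc()` fits, per CpG,

    beta_cs = sum_t mu_ct * f_ts + sum_t gamma_ct * f_ts * Age_s
              + theta_c * Sex_s + phi_c * Disease_s + eps_cs

by ordinary least squares. Design choices that were genuinely open:

- **No global intercept.** The fractions sum to one, so the baseline
  terms `mu_ct * f_ts` already span the constant; adding an intercept
  would make the design singular. The same reasoning applies in
  `residualize()`, which silently uses the fraction columns as the
  intercept when they sum to one.
- **Age centring.** Age is centred at its sample mean before the
  interaction terms are formed. This leaves every `gamma_ct` unchanged
  but decorrelates the baseline and slope estimates.
- **FDR within cell type.** Benjamini–Hochberg correction is applied to
  each cell type's `gamma` p-values separately, since DMCT counts are
  reported per cell type. Degrees of freedom are `n - (2T + #covariates)`
  with a two-sided t reference.
- **Rank deficiency.** Because the design is shared by all CpGs, a
  rank-deficient design (e.g. a near-constant fraction column) aborts
  the fit with an explanatory error rather than silently producing
  undefined p-values that would distort the BH denominator.

`fit_bulk_dmc()` replaces the interaction terms with a single
`gamma_c * Age_s` and keeps the fractions as covariates, yielding bulk
age-DMCs under the pseudo cell type `"bulk"`.

## Clocks: intrinsic, semi-intrinsic, nested CV

Both clock paradigms start from the age-DMCTs of a target cell type.
The **intrinsic** clock is trained and applied on residuals after
regressing out the cell-type fractions; the **semi-intrinsic** clock
uses the same CpGs on unadjusted betas, so it can exploit
composition-driven signal while remaining anchored on cell-type specific
CpGs. `train_clock()` fits the full elastic-net path (alpha 0.5, 100
lambdas spanning four decades below the null lambda — the conventional
path construction) and selects the penalty either by RMSE on an external
selection cohort (ties to the larger, sparser lambda) or by internal
10-fold cross-validation with a seeded fold assignment.

Standardization follows the standardized-residual workflow: with
`standardize = TRUE` each clock CpG is z-scored *within the cohort it is
applied to*, both at training and at prediction. The consequence —
predictions are cohort-relative — is deliberate and documented; it is
what makes a clock transferable across cohorts with different array
scales. Clock CpGs absent at prediction time are imputed with the
training mean (zero on the standardized scale) with a per-run warning;
if more than 20% are missing the prediction is refused as unreliable.
When the selection cohort is residualized, it is residualized with *its
own* fractions, the natural reading of the adjusted-data workflow.

`train_clock_cv10()` implements the single-cohort nested procedure used
for solid-tissue clocks: samples are split into 10 bags by stratified
sampling within age strata (quintiles — the bin width was unspecified,
and quintiles balance resolution against stratum size at n ≈ 200); per
fold, the interaction model is re-fitted on the other 9 bags and the
target cell type's DMCTs extracted; fold lists are truncated to the
minimum count k across folds, ranked by absolute t-statistic (the
significance ordering already used for DMCT calling); a lasso path on a
shared lambda grid is fitted per fold and evaluated on the held-out bag;
the lambda with minimal pooled out-of-bag RMSE wins, and the final model
is refitted at that lambda on all samples with the top-k DMCTs from a
full-data fit. This variant trains on raw (unstandardized) betas with
glmnet's internal standardization, because 21-sample leave-out bags make
per-cohort z-scoring unstable; the returned clock records
`standardize = FALSE` accordingly. `dmc_mode = "bulk"` swaps the
interaction model for the fraction-adjusted bulk model (the whole-tissue
variant of the same construction).

## Decomposing accuracy into intrinsic and extrinsic components

`quantify_components()` trains an unadjusted clock (data residualized
for nuisance covariates only) and an adjusted clock (additionally
residualized for all fractions), both elastic net with internal 10-fold
CV, applies them to test cohorts, and computes R² as the squared Pearson
correlation between predicted and chronological age. Squared PCC rather
than regression R² is used because it is invariant to the calibration
offset and slope that differ between cohorts; for a simple linear
regression of predicted on true age the two coincide anyway. The
intrinsic fraction is `R2_adj / R2_unadj`, the extrinsic fraction its
complement; when sampling noise pushes the ratio above 1 it is capped at
1 with a warning so both stay interpretable proportions. A clock whose
cross-validated penalty shrinks every weight to zero predicts a
constant; its R² is defined as 0.

## The mixture simulator

`simulate_mixture()` generates what the validation design requires: three
hypothetical blood cell types (granulocytes, monocytes, lymphocytes)
over 10,000 CpGs and 200 samples by default.

- **Basis profiles.** Every cell type's basis matrix is drawn i.i.d. per
  CpG *and sample* from a Beta distribution with mean 0.25
  ("unmethylated"); each cell type owns 1,000 marker CpGs that stay
  unmethylated in it but are drawn with mean 0.75 in the other two
  types. The default shapes are Beta(10, 30) and Beta(30, 10), chosen to
  realize the design means of 0.25 and 0.75 exactly (a Beta(a, b) mean is
  a/(a+b)); the shape pairs are exposed as parameters.
- **Planted age-DMCTs.** 1,000 lymphocyte CpGs receive M-values
  `M = log2(0.1/0.9) + (age - 30) * effS + N(0, effS)` with
  `effS = 0.1` per year, converted back to the beta scale. At age 30
  with the noise suppressed the planted beta is exactly 0.1 — the anchor
  the fidelity tests check. Ages default to Uniform(30, 75), preserving
  the age-30 anchor; a donor age vector can be supplied for
  bootstrapping when matching a real cohort's age distribution.
- **Fractions.** Dirichlet(30, 4, 16) — granulocyte-dominant, blood-like
  draws with mean fractions 0.60/0.08/0.32. In trend scenarios the
  lymphocyte fraction is coupled to age by a Gaussian-copula whole-row
  permutation targeting Spearman correlation ~0.5 by default
  (`fraction_age_rho`); permuting whole simplex rows preserves both the
  marginal fraction distribution and the unit row sums. The magnitude of
  the real-data trend is not printed anywhere usable, so the coupling
  strength is an explicit, documented parameter; "strong trend" analyses
  in the acceptance runs use `fraction_age_rho = 0.9`.
- **Scenarios.** (i) DMCTs disjoint from markers, no trend; (ii) same
  with trend; (iii)/(iv) 900 of the 1,000 DMCTs placed on lymphocyte
  markers (leaving 100 markers clean so a deconvolution reference can
  still be built), without/with trend.
- **Reference.** Built from an independent realization of the basis
  matrices, restricted to markers not used as DMCTs, averaged across
  samples — the reference is never contaminated by the planted signal.

What the simulator deliberately does *not* emulate: array artefacts
(probe-type bias, detection failures), correlated CpG blocks, nonlinear
age trajectories, and cell-type-specific measurement error. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated generative model, not robustness to real-array
technical structure.

`run_paradigm_benchmark()` wires it together: per scenario and
replicate, independent training and validation sets, deconvolution with
the held-out-marker reference, DMCT discovery, both clock paradigms with
internal CV, validation RMSE/PCC, and a two-tailed paired Wilcoxon test
between paradigms. The expected pattern — and what the acceptance suite
asserts at 20 replicates per scenario — is that semi-intrinsic clocks
win clearly when the lymphocyte fraction trends with age (scenarios
ii/iv) while intrinsic clocks are at least as good, within a year of
median RMSE, when it does not (i/iii).

## Meta-analysis and enrichment

`meta_inverse_variance()` implements fixed-effects inverse-variance
pooling and DerSimonian–Laird random effects from the closed-form
moment equations, with normal-reference p-values (the convention of the
standard meta-analysis tools), Cochran's Q, I² and a chi-squared
heterogeneity p. The permutation co-localization test draws same-size
CpG sets from the tested universe and uses add-one smoothing,
`p = (1 + #{null >= obs}) / (n_perm + 1)`, so empirical p-values are
never zero. Promoter windows are 1-based inclusive, ±1 kb around the
TSS, strand ignored (membership is defined by distance only).
Fraction outcomes are regressed untransformed in `study_effect()`; a
transform can be applied by the caller when desired.

## Numerical choices and degenerate inputs

- Beta values of exactly 0 or 1 are clipped to `[1e-6, 1 - 1e-6]` before
  the logit2 transform, keeping M-values finite without materially
  moving any value.
- k-NN imputation operates on CpG rows (probes as neighbours, k = 5 by
  default, Euclidean distance over mutually observed samples), matching
  the conventional orientation of array imputation; coverage thresholds
  are exposed because published QC rules range from 0.75 to 0.99.
- Zero-variance CpGs are left unscaled (divisor 1) during z-scoring.
- All randomized steps (fold and bag assignment, simulation draws,
  permutations) take explicit seeds and are bit-reproducible.

## Problem sizes used in the validation suite

The shipped tests validate the full-scale simulation design (10,000
CpGs, 200 samples) for the scenario benchmark (20 replicates per
scenario), DMCT recovery, the decomposition and the 210-sample nested CV
procedure, and use smaller instances of the same generative model
(~1,000–2,000 CpGs, 100–150 samples) for unit-level properties, which is
ample to pin down the algebraic and statistical behaviour being tested.

## Known limitations

- The decomposition attributes to "extrinsic" anything an
  fraction-adjusted clock loses, including signal merely collinear with
  fractions in a finite sample; with very strong fraction-age coupling
  the adjusted clock's cross-validated penalty may legitimately select
  the null model, making the split 0/100 rather than a graded estimate.
- Per-cohort standardization makes predictions cohort-relative;
  absolute-age calibration across platforms is out of scope.
- The robust IRLS deconvolver assumes the reference spans the observed
  profiles; unknown cell types bias fractions toward their nearest
  reference column.
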