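---
title: "Methods: inferring phage-host infection phenotypes from mutation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring phage-host infection phenotypes from mutation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery in `phinet`: the
phenotype definitions, the five feature models, how the LASSO fits and
bootstrap validation are configured, how driver mutations are called,
what the synthetic-data generator does and does not emulate, and the
numerical decisions that matter when reproducing results.

## Phenotypes

A plaque assay measures, for each phage *j* and host *i*, a plaque count
`q_ij` after `s_ij` five-fold dilution steps, with the same quantities on
the ancestral host as the reference. The efficiency of plating is

    e_ij = (q_ij / q_anc,j) * d^(s_ij - s_anc,j),     d = 5 by default.

`e_ij = 1` means the evolved host is infected exactly as efficiently as
the ancestor; `e_ij = 0` means no infection at any dilution. The
dilution ratio is a property of the assay design; `compute_eop()` takes
it as an argument so other dilution schemes can be used unchanged.

Two model responses are derived from the EOP grid:

* **POA** — `d_ij = 1{e_ij > 0}`, using the *strict* indicator. A zero
  is an exact zero (the phage formed no plaques), never a small epsilon:
  the assay's detection floor is part of the phenotype definition, and
  imputing a pseudo-count would silently move pairs between the two
  modeling tasks.
* **EFF** — `e'_ij = ln(e_ij)` for the pairs with `e_ij > 0` only.
  Zero-EOP pairs are excluded rather than imputed because the log is
  undefined there and the efficiency model is meaningful only where the
  host is susceptible. The natural log (not log10) is used throughout.

A Shapiro-Wilk test (`test_log_normality()`) reports how Gaussian the
`e'` distribution is. It is purely diagnostic: the result is logged in
the report bundle at the conventional 0.05 level but never gates any
step, because mild non-normality degrades the linear model gracefully
rather than invalidating it.

If both a precomputed EOP matrix and raw plaque tables are supplied to
`run_full_analysis()`, the precomputed matrix wins and a warning is
issued; a curated matrix is assumed to embody any assay-level QC already
performed. Assays whose ancestor reference produced zero plaques raise
an error — the EOP reference is undefined and no sensible default
exists.

## Feature models

With post-augmentation profile widths N (host) and M (phage), the five
per-pair encodings and their linear predictors are

| kind       | Φ_ij                                                    | width |
|------------|---------------------------------------------------------|-------|
| h          | γ + Σ α_l h_il                                          | N     |
| p          | γ + Σ α̃_k p_jk                                         | M     |
| linear     | γ + Σ α_l h_il + Σ α̃_k p_jk                            | N+M   |
| nonlinear  | γ + Σ_l Σ_k β_lk h_il p_jk                              | N·M   |
| mixed      | linear + nonlinear                                      | N+M+N·M |

The `h`/`p`/`linear` models assume additive effects of individual
mutations; `nonlinear` assumes the signal lives in co-occurring
host-phage mutation *pairs* (`h_il p_jk = 1` only when host i carries l
and phage j carries k); `mixed` nests both.

Implementation notes:

* The **ancestor trait** (`augment_ancestor()`) is an indicator column
  carried only by the ancestral strain, appended independently to both
  tables. It lets the all-zero ancestors participate in the regression
  with their own learnable offset.
* The bias γ is handled as an **unpenalized intercept** by the fitter,
  never as a design column — penalizing it would shrink the baseline
  infection rate toward 0.5 (POA) or 0 (EFF) for no reason.
* Features are **never standardized**: all predictors share the {0,1}
  scale, so coefficients are directly comparable in the importance
  analysis, and standardizing binary indicators would reweight the
  penalty by allele frequency.
* Pairwise columns are ordered host-major (`h1:p1, h1:p2, ...`), named
  `"hostmut:phagemut"`, and **all-zero columns are retained** (the LASSO
  leaves them at zero) so coefficient vectors align across bootstrap
  runs by position and name. The number of never-observed pairs is
  visible as the zero-column count of the design; with the study-shaped
  dimensions (19 x 177 columns) most pairwise combinations are never
  observed, which is exactly the underdetermination that makes the
  nonlinear model weak in validation.
* Designs are stored as sparse `dgCMatrix`; `predict_surface()`
  evaluates the matrix form `γ + Hα1' + 1(Pα̃)' + HBP'`, which the test
  suite checks against per-pair dot products to 1e-10.

## Fitting and validation

Both tasks use the LASSO (`glmnet` backend): logistic regression with
binomial deviance CV loss for POA, linear regression with MSE CV loss
for EFF. Decisions that are open in principle and fixed here:

* **Penalty grid**: 100 log-spaced values from λ_max (smallest penalty
  with an all-zero solution) down to λ_max·1e-4; the grid and CV losses
  are recorded in `cv_path`.
* **Selection**: the grid minimizer of mean 10-fold CV loss; no
  one-standard-error rule.
* **Folds**: a seeded uniform random partition of the training rows,
  unstratified. Stratification would change little at the prevalences
  involved (~40%) and an unstratified partition keeps the procedure
  identical for POA and EFF.
* **Classification threshold** 0.5 on the predicted probability,
  matching a symmetric count of false positives and false negatives.
* **Solver**: convergence threshold 1e-7, max 1e5 iterations for CV
  fits; fixed-penalty refits use 1e-10 / 1e7 so that the λ = 0 linear
  fit reproduces the normal-equations solution to better than 1e-8.

The bootstrap protocol (`run_bootstrap()`) draws, per run, a
with-replacement training sample the size of the eligible-pair set (all
U·V pairs for POA, the positive pairs for EFF); the never-drawn pairs
form the out-of-bag validation set (asymptotically (1−1/n)^n ≈ 36.8% of
pairs). CV penalty selection happens inside each run, on that run's
training sample only. Run r derives its seed as `master_seed + r`, so a
single integer reproduces all runs. A per-run paired **null model** is
fit on the same training sample: Bernoulli draws at the training
prevalence for POA (expected classification error `2p(1−p)`), the
training mean for EFF. Degenerate single-class POA training draws are
redrawn with an offset seed (up to 100 attempts) — possible at toy
sizes, vanishingly rare at realistic ones.

`compare_models()` uses a two-sided **paired Wilcoxon signed-rank
test** on per-run validation errors. The pairing is by construction
(shared splits), and the signed-rank test avoids a normality assumption
on error differences. The ten pairwise comparisons are reported raw,
without multiplicity correction, as a protocol-level choice mirrored in
the report bundle.

The **final model** (`fit_final()`) refits on all eligible pairs with λ
fixed to the arithmetic mean of the per-run selected penalties — on the
λ scale, not the log scale, taking "mean of the best penalty" at face
value. No CV is run in this step.

## Feature importance and driver calls

`feature_importance()` reports, per feature: the final-model
coefficient, the mean per-run coefficient, and the central-90% bootstrap
interval (5th/95th percentiles of the per-run coefficients). Two flags
are computed because both conventions are in circulation:

* `significant` — the central-90% interval excludes 0;
* `strict_significant` — even the minimum/maximum per-run coefficient
  does not cross 0.

Rows are ranked most-negative to most-positive **final** coefficient;
the bootstrap mean is exported alongside so either ordering can be
reconstructed. Importance is interpreted through |coefficient|, which is
meaningful here precisely because all features share the {0,1} scale.

## The synthetic-data generator

`generate_dataset()` builds datasets with known ground truth:

1. **Profiles** (`generate_profiles()`): strains are sampled at
   `n_days` checkpoints; each new strain copies a uniformly chosen
   earlier strain (or the ancestor) and adds `Poisson(rate × Δdays)` new
   mutations at sites it does not yet carry. This yields the temporally
   nested, lineage-structured incidence patterns characteristic of
   serial-transfer coevolution. Sites can be hit independently in
   different lineages — parallel evolution, as repeatedly documented for
   the receptor and host-range loci in phage-bacteria systems. An
   all-zero ancestor row is included and the ancestor trait appended.
2. **Truth** (`generate_truth()`): sparse planted coefficients at
   `effect_scale` magnitude, shared driver positions for the POA (logit
   scale) and EFF (log-EOP scale) truths. Host driver signs are negative
   with probability `host_sign_bias` (default 0.7) and phage driver
   signs positive with probability `phage_sign_bias` (default 0.7),
   emulating the qualitative asymmetry of coevolution — hosts mostly
   gain resistance, phages mostly gain host range — without asserting
   exact proportions. The POA intercept is calibrated by root-finding so
   the grid-mean infection probability equals `target_prevalence`
   (default 0.4, a typical positive-cell fraction for such assays);
   passing `gamma_poa` overrides the calibration.
3. **Phenotypes** (`generate_phenotypes()`): POA ~ Bernoulli(inverse
   logit of the POA truth); where POA = 1, `e' = Φ_eff + N(0, noise_sd)`
   and `e = exp(e')`; where POA = 0, `e = 0`. The EOP marginal is
   right-skewed with a long tail, as plaque-assay EOP distributions are.

Drivers are planted only on **identifiable** sites: strain frequency in
[0.15, 0.85] and an incidence pattern unique within the table. A site
perfectly linked to a passenger cannot be attributed to either locus by
any method, and a fixed or absent site carries no signal — planting
effects there would make "recovery" meaningless rather than hard.
Imperfectly correlated sites remain, so the benchmark still exercises
the hard part of sparse selection under linkage.

Scenario presets and their free parameters (chosen once as plausible for
a multi-week coevolution experiment, stated here for transparency):

* `toy` — 6 hosts × 5 phages, 4 + 6 sites, 3 checkpoints; smoke tests.
* `small` — 30 × 30 strains, 24 host and 30 phage sites over 6
  checkpoints at 1 mutation/lineage/day, 5 + 5 drivers of magnitude 2,
  log-scale noise 0.3; the parameter-recovery workhorse.
* `study-shaped` — 51 × 45 strains with 18 host and 176 phage sites
  (mirroring the dimensions of a published λ–*E. coli* coevolution
  dataset), host rate 0.4 vs phage rate 3 per day over 10 checkpoints.

What the generator does **not** emulate: selection and clonal
interference (lineage choice is neutral), recombination, measurement
error in plaque counting, mutation-type heterogeneity, and any
correlation between a mutation's lineage prevalence and its phenotypic
effect. Passing the recovery tests therefore shows the inference
machinery works when the additive generative assumptions hold; it does
not certify performance on real data, where epistasis and linkage are
not bounded by design.

## Problem sizes used by the test suite

The shipped tests run the recovery property at the `small` scale: 20
replicate datasets, 50 bootstrap runs each, POA task, linear vs
host-only vs phage-only vs null, asserting ≥ 80% of planted drivers
flagged significant with the correct sign and the linear model's mean
validation error below the alternatives. The acceptance script repeats
the computation at 5 replicates and adds an EFF run; both sizes were
chosen so a complete from-scratch reproduction stays comfortable on a
single CPU. The full 200-run protocol is what `run_full_analysis()`
defaults to for real analyses.

## Known limitations

* The nonlinear and mixed models are heavily underdetermined whenever
  most mutation pairs are never observed together; their coefficients
  should be read as one sparse solution among many compatible ones.
* LASSO under correlated predictors splits or swaps coefficients across
  bootstrap runs; strongly linked mutation groups can dilute each
  member's importance interval even when the group signal is strong.
  Reporting linkage groups rather than single sites would be a natural
  extension.
* The bootstrap pairs share training draws across feature kinds (same
  seeds) by design, which makes comparisons paired but means the 200
  runs are not independent replicates of anything.
* `shapiro.test` caps at n = 5000; larger EFF tables are diagnosed on
  their first 5000 values.
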