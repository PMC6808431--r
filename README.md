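# glycadecomp

GlycA is a serum NMR spectroscopy signal that predicts morbidity and
mortality from a remarkably wide range of causes, but it is a composite: the
signal aggregates the N-acetyl glycan resonances of several circulating
acute-phase glycoproteins — alpha-1 antitrypsin (AAT), alpha-1-acid
glycoprotein (AGP), haptoglobin (HP) and transferrin (TF) — whose
concentrations move on different time scales and in different directions.
Two people with identical GlycA can carry very different glycoprotein
profiles, so the biomarker's risk signal cannot be attributed to a molecule
without decomposing it.

`glycadecomp` implements that decomposition as a tested R pipeline for
biostatisticians working with NMR metabolomics and registry-linked cohorts:

1. **Imputation** — per glycoprotein, a lasso regression on 149
   log-standardised NMR features plus age, sex and BMI, tuned by 10-fold
   cross-validation over 100 penalties with the one-standard-error rule
   (`cv_train()`, `select_lambda_1se()`, `fit_final()`), serialised to JSON
   with both standardised and raw-scale coefficients, and applied to new
   cohorts with assay-range QC (`apply_model()`).
2. **Registry scan** — ICD-10 records aggregated to incident (first event in
   an 8-year follow-up) and prevalent (any prior event) status per outcome
   at three-digit code accuracy (`aggregate_outcomes()`); Cox
   proportional-hazards models per standard deviation of the log biomarker
   on the **age timescale** (entry at baseline age, Efron ties), adjusted
   for sex, smoking, BMI, blood pressure, alcohol, citrate, albumin and
   VLDL particle size (`cox_fit()`); inverse-variance fixed-effects
   meta-analysis across cohorts (`meta_fixed()`); Storey–Tibshirani
   q-values per biomarker × cohort family (`storey_qvalue()`); and a
   replication rule requiring FDR < 0.05/3 in both cohorts and the
   meta-analysis (`replication()`).
3. **Transcriptional stage** — probe-to-gene collapsing by per-sample
   maximum, correlation-ranked gene set enrichment with a literal
   running-sum score (hit: +r, miss: −1/N) normalised by 1,000 sample
   permutations, module eigengene regressions, and a core-membership
   permutation test (`collapse_probes()`, `normalise_and_test()`,
   `summary_expression()`, `module_regression()`, `core_membership()`).
4. **Synthetic cohorts** — a first-class generator (`generator_config()`,
   `generate_cohort()`, `generate_expression()`) reproducing the structure
   the analysis assumes: a multivariate log-normal glycoprotein/GlycA panel
   with a configurable correlation matrix, an NMR feature matrix whose
   best-linear-predictor R² for each log glycoprotein is calibrated
   numerically (0.43/0.64/0.56/0.18 by default), covariates, ICD-10 event
   records drawn from proportional hazards on the age timescale, and
   modular expression data with an AAT-linked eigengene.

The repository is organised as an analysis workflow: `analysis/01_simulate.R`
through `analysis/04_expression.R` are thin narrative drivers over the
package functions, writing their tables under `results/`.

## Worked example

```r
library(glycadecomp)

cfg   <- generator_config(n_samples = 10000, seed = 11)
panel <- generate_panel(cfg)                      # GlycA + 4 glycoproteins
nmr   <- generate_nmr(panel, cfg)                 # 149 features, zeros at LOD
cov   <- generate_covariates(cfg, panel)

rz <- replace_zeros(nmr)                          # detection-limit handling
ds <- log_standardize(cbind(rz$matrix, age = cov$age, sex = cov$sex,
                            bmi = cov$bmi), no_log = "age", passthrough = "sex")
tr <- train_imputation_model(ds$matrix, panel$AAT, preprocess = ds$params,
                             analyte = "AAT", seed = 3)
c(lambda = tr$lambda, features = tr$model$n_features,
  cv_rho = tr$model$cv_mean_rho, r2 = tr$metrics$r2)
#>      lambda    features      cv_rho          r2
#>  0.03179809 15.00000000  0.62936700  0.41906760
```

The cross-validated Spearman correlation (0.63) and explained variance
(r² = 0.42) match the generator's calibration target for AAT (R² = 0.43):
the one-standard-error penalty keeps 15 of 152 candidate inputs at
essentially no cost in accuracy. Running the registry scan on two synthetic
cohorts at the study sizes (4,540 + 7,321) recovers the generative heart
failure hazard,

```r
scan <- run_risk_scan(list(discovery = c1, replication = c2))   # see analysis/
scan[scan$outcome == "heart_failure" & scan$biomarker == "AAT" &
     scan$cohort == "meta", c("events", "hr", "ci_lo", "ci_hi", "q", "sig_rep")]
#>   events   hr ci_lo ci_hi        q sig_rep
#>      409 1.63  1.48  1.80  9.6e-22    TRUE
```

a meta-analysed HR of 1.63 (95% CI 1.48–1.80) against a generative value of
1.60 per SD of AAT, flagged significant and replicable at FDR < 0.05/3 in
both cohorts and the meta-analysis. When the scan instead uses *imputed*
AAT (as `analysis/03_risk_scan.R` does), hazard ratios attenuate toward the
null (1.43 for heart failure) — the regression-dilution effect of imputation
noise that the methods vignette discusses.

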