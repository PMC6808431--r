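---
title: "Decomposing the GlycA biomarker: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the GlycA biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glycadecomp)
```

## The problem

GlycA is a composite NMR signal arising from the N-acetyl glycan groups of
several circulating acute-phase glycoproteins (chiefly AAT, AGP, HP and TF).
It predicts long-term morbidity and mortality across many disease classes,
but the signal itself cannot say *which* glycoprotein carries the risk.
`glycadecomp` decomposes it in three statistical stages — glycoprotein
imputation from NMR features, a phenome-wide registry survival scan on the
imputed concentrations, and a transcriptional association stage — plus a
synthetic-cohort generator that gives every stage a ground truth. This
vignette records the models, their assumptions, the parameters that matter,
and the choices we made where the design was genuinely open.

## Imputation models

Each glycoprotein concentration is modelled on the natural-log scale as a
sparse linear function of 149 NMR metabolite features plus age, sex and BMI.
All concentrations and BMI are log transformed and standardised (sample SD,
n−1); age is standardised without a log; sex stays coded 1 = men, 2 = women.
Detection-limit zeros are first replaced by the feature's minimum positive
value in the same cohort — a proxy for the lower detection limit — and
samples with any missing feature are excluded. Derived-ratio features are
excluded by name because their missingness compounds that of numerator and
denominator.

The lasso penalty is tuned by 10-fold cross-validation over a descending
grid of 100 penalties (log-spaced from the smallest penalty that zeroes
every slope down to a 1e-4 ratio; the grid shape is configurable since the
procedure only pins the grid length). Fold assignment is a seeded random
permutation with fold sizes differing by at most one; the seed is recorded
in the `cv_report`. The standard error of the mean MSE at each penalty is
the SD of the 10 fold MSEs divided by √10. The selected penalty is the
largest one whose mean MSE lies within one standard error of the smallest
mean MSE — the sparsest model statistically indistinguishable from the best
one; ties resolve toward the larger penalty by construction of the
descending grid. Because NMR features are strongly collinear, re-running
training selects different feature subsets with similar accuracy; the
package therefore treats accuracy metrics (cross-validated Spearman ρ and
r²), not feature lists, as the stable quantities.

Fitted models store two coefficient conventions: standardised (relative
contributions) and raw (natural-log inputs, age in years, sex coded 1/2),
the latter used for imputation in new cohorts so that no cohort-dependent
re-standardisation is needed. Imputed values are exponentiated to the
natural scale and excluded when outside the assay validity ranges
(0.64–2.58 mg/L for AAT, 362–1,880 for AGP, 0.14–3.95 for HP); samples
missing any model input are flagged rather than imputed. TF is trained and
reported but not deployed to the risk scan: its accuracy (r² ≈ 0.18) is too
low for downstream use. The printed units mirror the assay conventions
as given (mg/L for AAT/HP/TF although the magnitudes suggest g/L); the
pipeline treats units as labels and never converts.

Fitting is delegated to `glmnet` (coordinate descent, `standardize = FALSE`
so our explicit standardisation is authoritative); the test suite verifies
the solutions against an independent hand-written coordinate-descent solver
to 1e-6 and the per-fold errors against an explicit fold-loop refit oracle.

## Registry outcomes and the survival scan

ICD-10 records (main and side diagnoses treated equally) are aggregated per
outcome — a three-digit code or an inclusive code range — into prevalent
status (any event at or before baseline; a boundary event counts as
prevalent) and incident status (earliest event in the 8-year follow-up).
Persons without an incident event are censored at baseline + 8 years. The
records carry no mortality distinction (first events are "discharge or
death" alike), so no competing-death censoring is applied. ICD-9-style
codes are rejected at load time with a pointer to the General Equivalence
Mapping conversion that must happen upstream.

An outcome enters the scan only with ≥ 20 incident cases in **every**
cohort, counted within each biomarker's successfully-imputed, non-pregnant
subset — so the tested outcome count differs between biomarkers. Cox models
use age as the time scale (delayed entry at baseline age), Efron tie
handling, and adjust for sex, smoking, BMI, systolic blood pressure,
alcohol, citrate, albumin and VLDL particle diameter (continuous covariates
log-standardised within cohort); prevalent status is adjusted for when the
cohort has ≥ 10 prevalent cases. Cohorts are pooled by inverse-variance
fixed-effects meta-analysis (weights 1/SE², normal p-value). The q-values
use the Storey–Tibshirani estimator: π0 from the smoother method
(π0(λ) = #{p > λ}/(m(1−λ)) over λ = 0.05…0.95, cubic smoothing spline
df = 3 evaluated at λ = 0.95, clamped to (0,1] with a warning; with < 10
p-values the estimate falls back to 1, reducing q to Benjamini–Hochberg).
The `qvalue` step-down q_i = min_{t ≥ p_i} π0·m·t/#{p ≤ t} is computed per
biomarker × cohort family after dropping non-converged or zero-event fits,
so family sizes are data-dependent. An association is *significant and
replicable* when q < 0.05/3 in both cohorts and the meta-analysis.
Sensitivity variants re-run the scan with CRP as an added covariate and in
the subset free of prevalent cases per outcome.

Two calibration facts worth knowing. First, under a 1,000-test global null
the probability of zero q < 0.05 discoveries is about 0.94–0.95 — this is a
property of BH-type control itself (P(any BH rejection) = α under
independence), not of the implementation, so "always zero discoveries"
should not be expected of any correct FDR procedure. Second, when the scan
analyses *imputed* rather than directly measured biomarkers, hazard ratios
attenuate toward the null in proportion to the imputation correlation
(regression dilution); the parameter-recovery simulations therefore define
the generative hazard on the biomarker actually analysed.

## Transcriptional stage

Probes are collapsed to genes by the per-sample maximum across a gene's
probes. Gene ranking residualises both expression and log AAT on age and
sex, then sorts genes by Pearson correlation (descending, ties broken by
gene id for determinism). The enrichment score walks the ranked list,
adding a gene's correlation when it belongs to the set and subtracting 1/N
(N = all ranked genes) otherwise; the score is the maximum of this running
sum, with the minimum also tracked for negative enrichment. This literal
rule differs from canonical GSEA (which normalises hits by the set's total
|r| and misses by 1/(N − set size)); a `canonical` switch provides the
classic weighting for comparison. One consequence of the literal rule is
that the running sum drifts to ≈ −1 under the null (misses dominate), so
the normalised score divides each side by the mean of the *same-side*
permutation scores: NES = ES_max / mean(permuted ES_max), or the analogous
negative ratio when |ES_min| exceeds ES_max. A positive NES then marks
enrichment among genes upregulated with AAT, null sets have NES ≈ 1 in
expectation, and empirical p-values use the add-one convention against the
same-side permutation distribution (1,000 sample shuffles of the
residualised AAT vector, re-ranking each time), BH-adjusted within each
gene set collection.

Module summary expression (the eigengene) is the first principal-component
score of the module's standardised probes, sign-aligned to correlate
positively with mean module expression and standardised; standardised log
AAT is regressed on it with age and sex adjustment, so the coefficient is
SDs of AAT per SD of coordinated expression, with Bonferroni thresholds
0.05/20 = 0.0025 and 0.05/346 ≈ 1.45e-4 for the two module families. Core
module membership compares each module probe's |correlation| with the
eigengene against the distribution of |correlation| between the eigengene
and all out-of-module probes (two-sided on |r|; add-one empirical p; BH
within module; FDR < 0.05). Note a structural caveat: a module's probes
participate in the principal component they are tested against, so even a
pure-noise module retains most of its probes — the test is calibrated for
held-out probes, and its value lies in ranking membership within genuinely
coherent modules, not in filtering noise modules.

## The synthetic-cohort generator

The generator defines the study conditions rather than adapting to them.
Glycoprotein/GlycA concentrations are multivariate log-normal: a Gaussian
copula on the log scale targets the correlation matrix (GlycA–AGP 0.64,
GlycA–HP 0.59, GlycA–AAT 0.33, GlycA–TF 0.26, AGP–TF −0.04;
inter-glycoprotein values in the moderate 0.12–0.52 band), and natural-scale
means/SDs (GlycA 1.30 ± 0.18 mmol/L, AAT 1.19 ± 0.20, AGP 789 ± 203,
HP 1.09 ± 0.49, TF 2.65 ± 0.38 mg/L) are matched by log-normal moment
inversion. Non-positive-semi-definite correlation matrices are rejected
outright, naming the offending eigenvalue — no silent nearest-PSD repair.

NMR features are linear in the standardised log analytes: the GlycA signal
itself (loading 1, noise SD 0.05), a block of 8 features per glycoprotein,
and ~116 nuisance features driven by 10 shared latent factors. The
per-block noise SDs are solved numerically (sweeps of univariate
root-finds on the closed-form population covariance) so the best linear
predictor of each log glycoprotein from all 149 features has exactly the
target R² (0.43/0.64/0.56/0.18) — the imputation stage's accuracy then has
a known truth. The lowest `detection_limit_quantile` fraction of each
feature is set to exactly zero to exercise the detection-limit path.

Event histories use an exponential (constant-in-age) baseline hazard per
outcome multiplied by exp(β·z) with z the standardised log biomarkers, so
left truncation at baseline age is exact by memorylessness; a prevalent
draw over the retrospective window (20 years for the discovery cohort, 10
for replication) uses the same rate. Each data product and each outcome has
its own seeded uniform stream, so adding outcomes never perturbs the panel
draws, and doubling a baseline rate under the same seed strictly grows the
incident set. Default baseline rates (0.002–0.005/year) give a few hundred
incident events per outcome at the study sizes — the regime the scan
operates in. A small fraction of women are flagged pregnant to exercise the
exclusion rule. Expression data are modular: probes = loading × latent +
noise, with the first module's latent profile correlating with AAT at the
generative effect (0.23 by default), duplicate-probe genes planted for the
collapsing step.

What the generator does **not** emulate: NMR spectral peaks, realistic
ICD-10 comorbidity structure, competing risks, assay batch effects, or the
heavy right tails of real acute-phase responses. Passing tests demonstrate
that the statistical machinery recovers known truths under the assumed
structure, not that the models are correct for any particular real cohort.

## Numerical choices and problem sizes

Lasso convergence thresholds are tightened (1e-11 in cross-validation,
1e-13 in final fits) so solutions agree with an independent
coordinate-descent solver to 1e-6. Spearman correlations of constant
predictions are defined as 0. The empirical permutation p-values use
(b+1)/(m+1). Model JSON serialises at full precision and round-trips
predictions to 1e-12. The test suite runs the survival parameter-recovery
at the full study sizes (4,540 + 7,321, 100 replicates), imputation
recovery at n = 10,000, GSEA planted-signal detection on 120-sample /
200-probe expression data over 100 seeds, and the end-to-end pipeline at
reduced cohort sizes (900/1,200) — sizes chosen to make the statistical
assertions sharp while keeping a full run in the low minutes on one core.

## Known limitations

Eligibility and family definitions assume exactly two cohorts plus their
meta-analysis for the replication flag. The Cox stage fits one biomarker at
a time (as the scan design requires) and offers no time-varying covariates
or competing-risk models. The GSEA stage permutes the residualised AAT
vector rather than re-residualising within each permutation; with age/sex
effects of realistic size this is indistinguishable in the permutation
distribution, but it is an approximation. π0 estimation inherits the
smoother's variance for small families; families under 10 tests fall back
to BH deliberately.
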