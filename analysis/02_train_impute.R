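#!/usr/bin/env Rscript
# Train glycoprotein imputation models and impute both cohorts.
#
# Uses the matched-assay training subset (first 626 participants of cohort
# 1): detection-limit zeros are replaced by the cohort minimum positive
# value, the 149 NMR features + age + sex + BMI are log-standardised, and a
# 10-fold cross-validated lasso with the one-standard-error rule is fit per
# glycoprotein. Models are serialised as JSON; AAT/AGP/HP are then imputed
# in both full cohorts on the raw-coefficient scale with assay-range QC
# (TF is trained for reporting but not deployed).

library(glycadecomp)

data_dir <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE)

read_cohort <- function(dir) {
  nmr_df <- read.csv(file.path(dir, "nmr.csv"), check.names = FALSE)
  nmr <- as.matrix(nmr_df[, -1])
  rownames(nmr) <- nmr_df$id
  list(panel = read.csv(file.path(dir, "panel.csv")),
       nmr = nmr,
       covariates = read.csv(file.path(dir, "covariates.csv")))
}

cohort1 <- read_cohort(file.path(data_dir, "cohort1"))
cohort2 <- read_cohort(file.path(data_dir, "cohort2"))

idx <- 1:626
rz <- replace_zeros(cohort1$nmr[idx, ])
ds <- log_standardize(cbind(rz$matrix, age = cohort1$covariates$age[idx],
                            sex = cohort1$covariates$sex[idx],
                            bmi = cohort1$covariates$bmi[idx]),
                      no_log = "age", passthrough = "sex")
ranges <- list(AAT = c(0.64, 2.58), AGP = c(362, 1880), HP = c(0.14, 3.95),
               TF = NULL)

acc <- NULL
models <- list()
for (a in c("AAT", "AGP", "HP", "TF")) {
  tr <- train_imputation_model(ds$matrix, cohort1$panel[[a]][idx],
                               preprocess = ds$params, analyte = a,
                               validity_range = ranges[[a]], seed = 1L)
  models[[a]] <- tr$model
  write_imputation_model(tr$model, file.path(out, paste0("model_", a, ".json")))
  acc <- rbind(acc, data.frame(analyte = a, n_features = tr$model$n_features,
                               cv_spearman = tr$model$cv_mean_rho,
                               in_sample_spearman = tr$metrics$rho,
                               r2 = tr$metrics$r2,
                               overfit_gap = tr$metrics$overfit_gap))
}
write.table(acc, file.path(out, "imputation_accuracy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Imputation accuracy (10-fold CV, 1-SE lasso):\n")
print(acc, row.names = FALSE, digits = 3)

for (cn in c("cohort1", "cohort2")) {
  co <- get(cn)
  rz_full <- replace_zeros(co$nmr)
  dat <- data.frame(rz_full$matrix, age = co$covariates$age,
                    sex = co$covariates$sex, bmi = co$covariates$bmi,
                    check.names = FALSE)
  imp <- data.frame(id = co$panel$id, GlycA = log(co$panel$GlycA))
  for (a in c("AAT", "AGP", "HP")) {
    res <- apply_model(models[[a]], dat)
    imp[[a]] <- log(res$value)
    cat(sprintf("%s %s: %d imputed, %d incomplete, %d out-of-range\n",
                cn, a, attr(res, "counts")[["ok"]],
                attr(res, "counts")[["incomplete-inputs"]],
                attr(res, "counts")[["out-of-range"]]))
  }
  write.table(imp, file.path(out, paste0("imputed_", cn, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
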