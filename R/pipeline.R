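# End-to-end orchestration: simulate -> preprocess -> train -> impute ->
# outcomes -> scan (meta/FDR/replication) -> expression -> report, with a
# single config, per-stage TSV outputs, a run manifest and a markdown
# summary. Stages communicate only through serialised files.

PIPELINE_STAGES <- c("simulate", "preprocess", "train", "impute", "outcomes",
                     "scan", "expression", "report")

GLYCOPROTEINS <- c("AAT", "AGP", "HP", "TF")

# Assay validity ranges on the natural scale (printed units).
VALIDITY_RANGES <- list(AAT = c(0.64, 2.58), AGP = c(362, 1880),
                        HP = c(0.14, 3.95), TF = NULL)

#' Build a pipeline configuration
#'
#' @param n_train matched-assay training subset size.
#' @param n_cohort1,n_cohort2 full cohort sizes for the two scan cohorts.
#' @param seed master seed for every stage.
#' @param stages named logical toggles over
#'   simulate/preprocess/train/impute/outcomes/scan/expression/report.
#' @param min_incident,min_prevalent,alpha,k,followup_years scan thresholds.
#' @param n_perm GSEA permutations.
#' @param generator list of overrides passed to [generator_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_train = 626L, n_cohort1 = 2000L,
                            n_cohort2 = 3000L, seed = 1L, stages = NULL,
                            min_incident = 20L, min_prevalent = 10L,
                            alpha = 0.05, k = 3, followup_years = 8,
                            n_perm = 200L, generator = list()) {
  st <- stats::setNames(rep(TRUE, length(PIPELINE_STAGES)), PIPELINE_STAGES)
  if (!is.null(stages)) st[names(stages)] <- stages
  stopifnot_msg(all(c(min_incident, min_prevalent, alpha, k, followup_years) > 0),
                "thresholds must be positive")
  cfg <- list(n_train = n_train, n_cohort1 = n_cohort1, n_cohort2 = n_cohort2,
              seed = as.integer(seed), stages = st,
              min_incident = min_incident, min_prevalent = min_prevalent,
              alpha = alpha, k = k, followup_years = followup_years,
              n_perm = n_perm, generator = generator)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# Design matrix for imputation training/evaluation: log-standardised NMR
# features + standardised age + sex (1/2, passthrough) + log-standardised
# BMI. With params supplied the stored transform is replayed.
build_design <- function(nmr_replaced, covariates, params = NULL) {
  mat <- cbind(nmr_replaced,
               age = covariates$age, sex = as.numeric(covariates$sex),
               bmi = covariates$bmi)
  log_standardize(mat, params = params, no_log = "age", passthrough = "sex")
}

#' Run the decomposition pipeline
#'
#' Executes the enabled stages in dependency order, writing per-stage TSVs,
#' a JSON run manifest (versions, seeds, exclusion counts) and a markdown
#' summary whose numbers are read back from the stage TSVs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the manifest and key result tables.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("glycadecomp")),
                   seed = config$seed, stages = list(), counts = list())
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      manifest$stages[[name]] <<- "disabled"
      return(invisible(NULL))
    }
    ok <- tryCatch({
      fun()
      TRUE
    }, error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
                 file.path(out_dir, "manifest.json"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- "completed"
    invisible(ok)
  }

  run_stage("simulate", function() {
    gen1 <- utils::modifyList(list(n_samples = config$n_cohort1,
                                   seed = config$seed,
                                   retrospective_years = 20,
                                   followup_years = config$followup_years),
                              config$generator)
    gen2 <- utils::modifyList(list(n_samples = config$n_cohort2,
                                   seed = config$seed + 1L,
                                   retrospective_years = 10,
                                   followup_years = config$followup_years),
                              config$generator)
    state$cohort1 <- generate_cohort(do.call(generator_config, gen1))
    state$cohort2 <- generate_cohort(do.call(generator_config, gen2))
    write_cohort_csv(state$cohort1, file.path(out_dir, "cohort1"))
    write_cohort_csv(state$cohort2, file.path(out_dir, "cohort2"))
  })

  run_stage("preprocess", function() {
    co <- state$cohort1
    idx <- seq_len(min(config$n_train, nrow(co$panel)))
    rz <- replace_zeros(co$nmr[idx, , drop = FALSE])
    ds <- build_design(rz$matrix, co$covariates[idx, , drop = FALSE])
    state$train_design <- ds$matrix
    state$train_params <- ds$params
    state$train_panel <- co$panel[idx, , drop = FALSE]
    manifest$counts$zeros_replaced_training <<- length(rz$params)
    write_tsv(data.frame(feature = names(rz$params), min_positive = rz$params),
              file.path(out_dir, "zero_replacements.tsv"))
  })

  run_stage("train", function() {
    state$models <- list()
    cv_rows <- list()
    for (a in GLYCOPROTEINS) {
      tr <- train_imputation_model(
        state$train_design, state$train_panel[[a]],
        preprocess = state$train_params, analyte = a,
        unit = if (a == "GlycA") "mmol/L" else "mg/L",
        validity_range = VALIDITY_RANGES[[a]], seed = config$seed)
      state$models[[a]] <- tr$model
      write_imputation_model(tr$model, file.path(out_dir, paste0("model_", a, ".json")))
      cv_rows[[a]] <- data.frame(
        analyte = a, lambda = tr$lambda, n_features = tr$model$n_features,
        cv_mean_rho = tr$model$cv_mean_rho, in_sample_rho = tr$metrics$rho,
        r2 = tr$metrics$r2, overfit_gap = tr$metrics$overfit_gap)
    }
    write_tsv(do.call(rbind, cv_rows), file.path(out_dir, "imputation_accuracy.tsv"))
  })

  run_stage("impute", function() {
    # TF is trained and reported but not deployed to the risk scan.
    deploy <- c("AAT", "AGP", "HP")
    for (cn in c("cohort1", "cohort2")) {
      co <- state[[cn]]
      rz <- replace_zeros(co$nmr)
      dat <- data.frame(rz$matrix, age = co$covariates$age,
                        sex = co$covariates$sex, bmi = co$covariates$bmi,
                        check.names = FALSE)
      rownames(dat) <- co$panel$id
      bm <- data.frame(id = co$panel$id)
      qc <- list()
      for (a in deploy) {
        imp <- apply_model(state$models[[a]], dat)
        bm[[a]] <- log(imp$value)
        qc[[a]] <- data.frame(cohort = cn, analyte = a,
                              t(as.matrix(attr(imp, "counts"))))
      }
      bm$GlycA <- log(co$panel$GlycA)
      state[[paste0("biomarkers_", cn)]] <- bm
      write_tsv(bm, file.path(out_dir, paste0("imputed_", cn, ".tsv")))
      write_tsv(do.call(rbind, qc), file.path(out_dir, paste0("impute_qc_", cn, ".tsv")))
    }
  })

  run_stage("outcomes", function() {
    hs <- state$cohort1$config$hazard_spec
    defs <- stats::setNames(lapply(hs, `[[`, "codes"), names(hs))
    for (cn in c("cohort1", "cohort2")) {
      co <- state[[cn]]
      baseline <- data.frame(id = co$covariates$id,
                             baseline_age = co$covariates$age)
      tab <- aggregate_outcomes(co$records, defs, baseline,
                                followup_years = config$followup_years)
      state[[paste0("outcomes_", cn)]] <- tab
      write_tsv(outcome_counts(tab), file.path(out_dir, paste0("outcome_counts_", cn, ".tsv")))
    }
  })

  run_stage("scan", function() {
    cohorts <- list(
      cohort1 = list(covariates = prepare_cox_covariates(state$cohort1$covariates),
                     outcomes = state$outcomes_cohort1,
                     biomarkers = state$biomarkers_cohort1),
      cohort2 = list(covariates = prepare_cox_covariates(state$cohort2$covariates),
                     outcomes = state$outcomes_cohort2,
                     biomarkers = state$biomarkers_cohort2))
    scan <- run_risk_scan(cohorts, min_incident = config$min_incident,
                          min_prevalent_adjust = config$min_prevalent,
                          alpha = config$alpha, k = config$k)
    state$scan <- scan
    for (b in unique(scan$biomarker)) {
      write_tsv(scan[scan$biomarker == b, , drop = FALSE],
                file.path(out_dir, paste0("hazard_", b, ".tsv")))
    }
    write_tsv(scan, file.path(out_dir, "hazard_all.tsv"))
  })

  run_stage("expression", function() {
    gcfg <- do.call(generator_config,
                    utils::modifyList(list(seed = config$seed), config$generator))
    ex <- generate_expression(gcfg)
    gene_mat <- collapse_probes(ex$expr, ex$annot)
    module_genes <- lapply(ex$modules, function(p)
      unique(ex$annot$gene[match(p, ex$annot$probe)]))
    set.seed(child_seed(config$seed, 7L))
    decoys <- lapply(1:5, function(i)
      sample(rownames(gene_mat), 25L))
    names(decoys) <- paste0("decoy", 1:5)
    colls <- list(modules = module_genes, decoys = decoys)
    gsea <- normalise_and_test(gene_mat, ex$aat, ex$age, ex$sex, colls,
                               n_perm = config$n_perm, seed = config$seed)
    write_tsv(gsea, file.path(out_dir, "gsea.tsv"))
    mods <- lapply(names(ex$modules), function(m) {
      se <- summary_expression(ex$expr, ex$modules[[m]])
      cbind(module = m,
            module_regression(ex$aat, se, ex$age, ex$sex,
                              family_size = length(ex$modules),
                              standardize = FALSE))
    })
    write_tsv(do.call(rbind, mods), file.path(out_dir, "module_assoc.tsv"))
    core <- core_membership(ex$expr, ex$modules[[1L]])
    write_tsv(core, file.path(out_dir, "core_membership.tsv"))
  })

  run_stage("report", function() {
    lines <- c("# GlycA decomposition pipeline summary", "")
    acc_path <- file.path(out_dir, "imputation_accuracy.tsv")
    if (file.exists(acc_path)) {
      acc <- read_tsv(acc_path)
      lines <- c(lines, "## Imputation accuracy (10-fold CV, 1-SE lasso)", "",
                 "| analyte | features | CV Spearman | r2 |",
                 "|---|---|---|---|",
                 sprintf("| %s | %d | %.2f | %.2f |", acc$analyte,
                         acc$n_features, acc$cv_mean_rho, acc$r2), "")
    }
    scan_path <- file.path(out_dir, "hazard_all.tsv")
    if (file.exists(scan_path)) {
      sc <- read_tsv(scan_path)
      rep_rows <- sc[sc$cohort == "meta" & !is.na(sc$sig_rep) & sc$sig_rep, ,
                     drop = FALSE]
      lines <- c(lines, "## Significant and replicable associations (meta-analysis)",
                 "",
                 "| biomarker | outcome | events | HR | 95% CI | FDR |",
                 "|---|---|---|---|---|---|",
                 if (nrow(rep_rows) > 0)
                   sprintf("| %s | %s | %d | %.2f | %.2f-%.2f | %.2g |",
                           rep_rows$biomarker, rep_rows$outcome, rep_rows$events,
                           rep_rows$hr, rep_rows$ci_lo, rep_rows$ci_hi,
                           rep_rows$q)
                 else "| - | none | - | - | - | - |", "")
    }
    gsea_path <- file.path(out_dir, "gsea.tsv")
    if (file.exists(gsea_path)) {
      gs <- read_tsv(gsea_path)
      sig <- gs[gs$significant, , drop = FALSE]
      lines <- c(lines, "## Gene sets enriched for AAT-associated expression", "",
                 "| collection | gene set | size | NES | FDR |",
                 "|---|---|---|---|---|",
                 if (nrow(sig) > 0)
                   sprintf("| %s | %s | %d | %.2f | %.2g |", sig$collection,
                           sig$gene_set, sig$size, sig$nes, sig$fdr)
                 else "| - | none | - | - | - |", "")
    }
    writeLines(lines, file.path(out_dir, "summary.md"))
  })

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(manifest = manifest,
                 scan = if (exists("scan", envir = state)) state$scan else NULL))
}
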