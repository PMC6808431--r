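# Per-biomarker, per-outcome Cox proportional-hazards scan on the age
# timescale (left truncation at baseline age, Efron ties), inverse-variance
# fixed-effects meta-analysis across cohorts, Storey-Tibshirani positive-FDR
# q-values per (biomarker, cohort) family, the dual-cohort replication rule,
# and CRP / prevalent-exclusion sensitivity variants.

COX_COVARIATES <- c("sex", "smoking", "bmi", "sbp", "alcohol", "citrate",
                    "albumin", "vldl_d")

#' Prepare covariates for the Cox models
#'
#' Continuous covariates (BMI, systolic blood pressure, alcohol, citrate,
#' albumin, VLDL particle diameter, CRP) are log transformed and
#' standardised to SD 1 within the cohort; sex (1/2) and current smoking
#' stay categorical.
#'
#' @param covariates data.frame from [generate_covariates()] or equivalent.
#' @return data.frame with the transformed columns.
#' @export
prepare_cox_covariates <- function(covariates) {
  out <- covariates
  for (v in c("bmi", "sbp", "alcohol", "citrate", "albumin", "vldl_d", "crp")) {
    if (v %in% names(out)) out[[v]] <- scale(log(out[[v]]))[, 1L]
  }
  out$sex <- factor(out$sex, levels = c(1L, 2L))
  out
}

#' Cox proportional-hazards fit for one biomarker and outcome
#'
#' Age is the time scale: entry at baseline age, exit at first-event or
#' censoring age, Efron tie handling. The biomarker must be supplied
#' log-transformed and standardised so the coefficient is per-SD. Prevalent
#' status enters as a covariate when `adjust_prevalent`; CRP when
#' `adjust_crp`.
#'
#' @param df one row per person with columns `baseline_age`, `censor_age`,
#'   `incident`, `biomarker`, `prevalent`, the covariates in
#'   [prepare_cox_covariates()] form, and `crp` if used.
#' @param adjust_prevalent,adjust_crp covariate switches.
#' @param covariate_names adjustment covariates present in `df`.
#' @return one-row data.frame (beta, se, hr, ci_lo, ci_hi, p, n, events,
#'   prevalent, converged) or NULL with a message when there are no events.
#' @export
cox_fit <- function(df, adjust_prevalent = TRUE, adjust_crp = FALSE,
                    covariate_names = COX_COVARIATES) {
  events <- sum(df$incident)
  if (events == 0) {
    message("cox_fit: no incident events; fit skipped")
    return(NULL)
  }
  covs <- intersect(covariate_names, names(df))
  terms <- c("biomarker", covs)
  if (adjust_prevalent) terms <- c(terms, "prevalent")
  if (adjust_crp) terms <- c(terms, "crp")
  f <- stats::as.formula(paste(
    "survival::Surv(baseline_age, censor_age, incident) ~",
    paste(terms, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(f, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|loglik", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  beta <- s$coefficients["biomarker", "coef"]
  se <- s$coefficients["biomarker", "se(coef)"]
  data.frame(beta = beta, se = se, hr = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             p = 2 * stats::pnorm(-abs(beta / se)),
             n = nrow(df), events = events, prevalent = sum(df$prevalent),
             converged = converged)
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Pooled beta = sum(w * beta) / sum(w) with w = 1/SE^2; pooled
#' SE = 1/sqrt(sum(w)); two-sided normal p-value.
#'
#' @param beta,se per-cohort log hazard ratios and standard errors.
#' @return list with `beta`, `se`, `p`, `hr`, `ci_lo`, `ci_hi`, `note`.
#' @export
meta_fixed <- function(beta, se) {
  stopifnot_msg(length(beta) == length(se) && length(beta) >= 1,
                "beta and se must be matched and non-empty")
  note <- NULL
  if (length(beta) == 1L) {
    note <- "single estimate returned as-is"
    pooled_b <- beta
    pooled_se <- se
  } else {
    w <- 1 / se^2
    pooled_b <- sum(w * beta) / sum(w)
    pooled_se <- 1 / sqrt(sum(w))
  }
  list(beta = pooled_b, se = pooled_se,
       p = 2 * stats::pnorm(-abs(pooled_b / pooled_se)),
       hr = exp(pooled_b), ci_lo = exp(pooled_b - 1.96 * pooled_se),
       ci_hi = exp(pooled_b + 1.96 * pooled_se), note = note)
}

#' Storey-Tibshirani positive-FDR q-values
#'
#' pi0 is estimated by the smoother method: pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda)) over the lambda grid, a cubic
#' smoothing spline (df = 3) evaluated at the largest lambda, clamped to
#' (0, 1] with a warning if outside. With fewer than 10 p-values (or
#' `pi0 = 1` forced) the estimate falls back to 1, making the q-values
#' identical to Benjamini-Hochberg adjusted p-values. q_i is the step-down
#' minimum over thresholds t >= p_i of pi0 * m * t / #\{p <= t\}.
#'
#' @param p p-values in \[0, 1\].
#' @param lambda pi0 tuning grid.
#' @param pi0 optional forced pi0 (e.g. 1 for BH behaviour).
#' @return list with `p`, `pi0`, `q`, `lambda`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  stopifnot_msg(length(p) > 0, "empty p-value vector")
  stopifnot_msg(all(p >= 0 & p <= 1), "p-values must be in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10L) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      if (pi0 <= 0 || pi0 > 1) {
        warning("pi0 estimate outside (0, 1]; clamped to 1")
        pi0 <- 1
      }
    }
  }
  ord <- order(p)
  q_ord <- pi0 * m * p[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q_ord <- pmin(q_ord, 1)
  q <- numeric(m)
  q[ord] <- q_ord
  list(p = p, pi0 = pi0, q = q, lambda = lambda)
}

#' Dual-cohort replication rule
#'
#' An association is significant and replicable when its FDR-adjusted
#' p-value is below `alpha / k` (0.05/3 = 0.0167 with the default Bonferroni
#' correction for three glycoproteins) in both cohorts and in the
#' meta-analysis.
#'
#' @param q_cohort1,q_cohort2,q_meta FDR-adjusted p-values (vectorised).
#' @param alpha,k significance level and Bonferroni divisor.
#' @return logical vector.
#' @export
replication <- function(q_cohort1, q_cohort2, q_meta, alpha = 0.05, k = 3) {
  thr <- alpha / k
  q_cohort1 < thr & q_cohort2 < thr & q_meta < thr
}

# Assemble the per-person analysis frame for one biomarker and outcome.
cox_frame <- function(biomarker_values, outcome_tab, covariates, outcome) {
  sub <- outcome_tab[outcome_tab$outcome == outcome, , drop = FALSE]
  df <- merge(covariates, sub, by = "id")
  df$biomarker <- biomarker_values[df$id]
  df <- df[!is.na(df$biomarker), , drop = FALSE]
  df$baseline_age <- df$age
  df$biomarker <- scale(df$biomarker)[, 1L]
  df
}

#' Phenome-wide Cox scan with meta-analysis, FDR and replication
#'
#' For each biomarker: restricts each cohort to persons with a
#' successfully-imputed (non-missing) biomarker value, excludes pregnant
#' women, applies the eligibility rule (>= `min_incident` incident cases in
#' every cohort), fits the Cox model per outcome per cohort
#' (prevalent-adjusted where the cohort has >= `min_prevalent_adjust`
#' prevalent cases), pools cohorts by fixed-effects meta-analysis, computes
#' Storey q-values within each (biomarker, cohort) family — non-converged
#' fits are excluded from the family first — and flags replicated
#' associations.
#'
#' @param cohorts named list (>= 2) with, per cohort: `covariates`
#'   (prepared via [prepare_cox_covariates()], including `age` and
#'   `pregnant`), `outcomes` ([aggregate_outcomes()] output), `biomarkers`
#'   (data.frame: `id` plus one column of log-scale values per biomarker,
#'   NA where imputation failed).
#' @param biomarker_names biomarkers to scan (default: all shared columns).
#' @param min_incident,min_prevalent_adjust eligibility thresholds.
#' @param alpha,k replication rule parameters.
#' @param adjust_crp add CRP to every model (sensitivity variant).
#' @param exclude_prevalent drop prevalent cases of each outcome instead of
#'   adjusting for them (sensitivity variant).
#' @return data.frame with one row per biomarker x outcome x
#'   (cohort | "meta"): n, events, prevalent, beta, se, hr, ci, p, q,
#'   significance and replication flags.
#' @export
run_risk_scan <- function(cohorts, biomarker_names = NULL,
                          min_incident = 20L, min_prevalent_adjust = 10L,
                          alpha = 0.05, k = 3, adjust_crp = FALSE,
                          exclude_prevalent = FALSE) {
  stopifnot_msg(length(cohorts) >= 2L, "run_risk_scan requires >= 2 cohorts")
  if (is.null(biomarker_names)) {
    biomarker_names <- Reduce(intersect, lapply(cohorts, function(co)
      setdiff(names(co$biomarkers), "id")))
  }
  rows <- list()
  for (b in biomarker_names) {
    # biomarker-specific analysis subsets: imputed and not pregnant
    subs <- lapply(cohorts, function(co) {
      ok_ids <- co$biomarkers$id[!is.na(co$biomarkers[[b]])]
      keep <- co$covariates$id %in% ok_ids & co$covariates$pregnant == 0L
      ids <- co$covariates$id[keep]
      list(covariates = co$covariates[keep, , drop = FALSE],
           outcomes = co$outcomes[co$outcomes$id %in% ids, , drop = FALSE],
           values = stats::setNames(co$biomarkers[[b]][match(ids, co$biomarkers$id)], ids))
    })
    elig <- eligibility(lapply(subs, `[[`, "outcomes"),
                        min_incident = min_incident,
                        min_prevalent_adjust = min_prevalent_adjust)
    tested <- elig$outcome[elig$analysed]
    per_cohort <- list()
    for (cn in names(subs)) {
      res <- lapply(tested, function(o) {
        df <- cox_frame(subs[[cn]]$values, subs[[cn]]$outcomes,
                        subs[[cn]]$covariates, o)
        if (exclude_prevalent) {
          df <- df[df$prevalent == 0L, , drop = FALSE]
          adj_prev <- FALSE
        } else {
          adj_prev <- elig[[paste0("adjust_prevalent_", cn)]][match(o, elig$outcome)]
        }
        fit <- if (sum(df$incident) == 0) NULL else
          cox_fit(df, adjust_prevalent = adj_prev, adjust_crp = adjust_crp)
        if (is.null(fit)) return(NULL)
        cbind(data.frame(biomarker = b, outcome = o, cohort = cn), fit)
      })
      res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
      if (!is.null(res) && nrow(res) > 0) {
        fam <- res$converged
        res$q <- NA_real_
        if (any(fam)) res$q[fam] <- storey_qvalue(res$p[fam])$q
        per_cohort[[cn]] <- res
      }
    }
    # meta-analysis family
    common <- Reduce(intersect, lapply(per_cohort, `[[`, "outcome"))
    meta <- lapply(common, function(o) {
      ests <- lapply(per_cohort, function(r) r[r$outcome == o, , drop = FALSE])
      ok <- vapply(ests, function(e) nrow(e) == 1 && e$converged, TRUE)
      if (!all(ok)) return(NULL)
      mb <- vapply(ests, `[[`, 0, "beta")
      ms <- vapply(ests, `[[`, 0, "se")
      mm <- meta_fixed(mb, ms)
      data.frame(biomarker = b, outcome = o, cohort = "meta",
                 beta = mm$beta, se = mm$se, hr = mm$hr, ci_lo = mm$ci_lo,
                 ci_hi = mm$ci_hi, p = mm$p,
                 n = sum(vapply(ests, `[[`, 0, "n")),
                 events = sum(vapply(ests, `[[`, 0, "events")),
                 prevalent = sum(vapply(ests, `[[`, 0, "prevalent")),
                 converged = TRUE)
    })
    meta <- do.call(rbind, meta[!vapply(meta, is.null, TRUE)])
    if (!is.null(meta) && nrow(meta) > 0) {
      meta$q <- storey_qvalue(meta$p)$q
      per_cohort$meta <- meta
    }
    all_b <- do.call(rbind, lapply(per_cohort, function(r)
      r[, c("biomarker", "outcome", "cohort", "n", "events", "prevalent",
            "beta", "se", "hr", "ci_lo", "ci_hi", "p", "q", "converged")]))
    # replication flag over the cohort pair + meta
    cns <- names(cohorts)
    if (!is.null(meta)) {
      thr <- alpha / k
      all_b$sig <- all_b$q < thr
      rep_map <- vapply(unique(all_b$outcome), function(o) {
        qs <- vapply(c(cns, "meta"), function(cn) {
          r <- all_b[all_b$outcome == o & all_b$cohort == cn, "q"]
          if (length(r) == 1) r else NA_real_
        }, 0)
        !anyNA(qs) && all(qs < thr)
      }, TRUE)
      all_b$sig_rep <- rep_map[all_b$outcome]
    } else {
      all_b$sig <- all_b$sig_rep <- NA
    }
    rows[[b]] <- all_b
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' CRP and prevalent-exclusion sensitivity analyses
#'
#' Re-runs the scan (a) with CRP as an additional covariate and (b) in the
#' subset of individuals without prevalent cases of each outcome, and pairs
#' the meta-analysed hazard ratios with the base scan's for attenuation
#' assessment.
#'
#' @param cohorts as in [run_risk_scan()].
#' @param base optional precomputed base scan (recomputed if NULL).
#' @param ... passed to [run_risk_scan()].
#' @return list with `base`, `crp`, `no_prevalent` scan tables and
#'   `paired`, a data.frame of meta HRs side by side.
#' @export
sensitivity_suite <- function(cohorts, base = NULL, ...) {
  if (is.null(base)) base <- run_risk_scan(cohorts, ...)
  crp <- run_risk_scan(cohorts, adjust_crp = TRUE, ...)
  noprev <- run_risk_scan(cohorts, exclude_prevalent = TRUE, ...)
  bm <- base[base$cohort == "meta", c("biomarker", "outcome", "hr", "se")]
  cm <- crp[crp$cohort == "meta", c("biomarker", "outcome", "hr", "se")]
  nm <- noprev[noprev$cohort == "meta", c("biomarker", "outcome", "hr", "se")]
  paired <- merge(merge(bm, cm, by = c("biomarker", "outcome"),
                        suffixes = c("_base", "_crp")),
                  stats::setNames(nm, c("biomarker", "outcome", "hr_noprev",
                                        "se_noprev")),
                  by = c("biomarker", "outcome"))
  list(base = base, crp = crp, no_prevalent = noprev, paired = paired)
}
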