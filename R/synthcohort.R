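# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: a correlated glycoprotein/GlycA panel on the
# natural concentration scale, an NMR feature matrix linearly informative
# about the glycoproteins at calibrated accuracy, baseline covariates,
# proportional-hazards event histories on the age timescale, and modular
# gene expression data. Every generative quantity is returned in `truth`.

ANALYTES <- c("GlycA", "AAT", "AGP", "HP", "TF")

#' Default glycoprotein/GlycA log-scale correlation matrix
#'
#' GlycA correlations with AGP (0.64), HP (0.59), AAT (0.33), and TF (0.26)
#' follow the reference population estimates; inter-glycoprotein
#' correlations sit in the moderate positive range with AGP and TF
#' uncorrelated (-0.04).
#'
#' @return 5x5 symmetric correlation matrix over GlycA, AAT, AGP, HP, TF.
#' @export
default_target_corr <- function() {
  C <- diag(5)
  dimnames(C) <- list(ANALYTES, ANALYTES)
  set_pair <- function(a, b, r) {
    C[a, b] <<- r
    C[b, a] <<- r
  }
  set_pair("GlycA", "AAT", 0.33)
  set_pair("GlycA", "AGP", 0.64)
  set_pair("GlycA", "HP", 0.59)
  set_pair("GlycA", "TF", 0.26)
  set_pair("AAT", "AGP", 0.32)
  set_pair("AAT", "HP", 0.25)
  set_pair("AAT", "TF", 0.12)
  set_pair("AGP", "HP", 0.52)
  set_pair("AGP", "TF", -0.04)
  set_pair("HP", "TF", 0.15)
  C
}

# Nightingale-style feature names for the NMR matrix. The first name is the
# GlycA signal itself; the remainder are plausible platform measure names.
nmr_feature_names <- function(n = 149L) {
  sizes <- c("XXL", "XL", "L", "M", "S", "XS")
  lipo <- as.vector(outer(sizes, c("VLDL", "LDL", "HDL"),
                          function(s, l) paste0(s, "_", l)))
  lipo_attrs <- as.vector(outer(lipo, c("P", "L", "PL", "C", "CE", "FC", "TG"),
                                paste, sep = "_"))
  small <- c("Serum_C", "Serum_TG", "VLDL_C", "LDL_C", "HDL_C", "HDL2_C",
             "HDL3_C", "Remnant_C", "EstC", "FreeC", "TotPG", "PC", "SM",
             "TotCho", "ApoA1", "ApoB", "TotFA", "DHA", "LA", "FAw3", "FAw6",
             "PUFA", "MUFA", "SFA", "Glc", "Lac", "Pyr", "Cit", "Glol",
             "Ala", "Gln", "Gly", "His", "Ile", "Leu", "Val", "Phe", "Tyr",
             "Ace", "AcAce", "bOHBut", "Crea", "Alb", "VLDL_D", "LDL_D",
             "HDL_D", "IDL_P", "IDL_L", "IDL_C", "IDL_TG")
  pool <- unique(c("GlycA", lipo_attrs, small))
  if (length(pool) < n) {
    pool <- c(pool, sprintf("NMR_%03d", seq_len(n - length(pool))))
  }
  pool[seq_len(n)]
}

#' Build a synthetic-cohort generator configuration
#'
#' Defaults encode the study conditions the pipeline is designed for:
#' concentration scales of GlycA 1.30 +/- 0.18 mmol/L, AAT 1.19 +/- 0.20,
#' AGP 789 +/- 203, HP 1.09 +/- 0.49 and TF 2.65 +/- 0.38 mg/L; 149 NMR
#' features whose best linear predictors of the log glycoproteins reach
#' population R^2 of 0.43/0.64/0.56/0.18 (AAT/AGP/HP/TF); an 8-year
#' follow-up; and outcome hazards with per-SD log hazard ratios matching the
#' headline associations (e.g. heart failure at HR 1.60 per SD of AAT).
#'
#' @param n_samples number of cohort participants.
#' @param target_corr 5x5 log-scale correlation matrix (GlycA, AAT, AGP, HP,
#'   TF); must be symmetric with unit diagonal and positive semi-definite.
#' @param conc_means,conc_sds natural-scale concentration means and SDs.
#' @param n_nmr_features number of NMR features (149 by default).
#' @param target_r2 population best-linear-predictor R^2 of each log
#'   glycoprotein given all NMR features; used to calibrate feature noise.
#' @param block_size informative features per glycoprotein.
#' @param detection_limit_quantile fraction of each feature's lowest values
#'   forced to exactly zero (simulated detection limit).
#' @param covariate_params list overriding covariate distributions.
#' @param hazard_spec named list of outcomes, each a list with `codes`
#'   (ICD-10 code or range), `baseline_rate` (events/year at z = 0) and
#'   `log_hr` (named per-SD log hazard ratios over biomarkers).
#' @param followup_years,retrospective_years incident follow-up and
#'   retrospective (prevalent) window lengths in years.
#' @param expression list overriding the expression-stage generator
#'   (n_samples, n_probes, module_sizes, aat_assoc, loading, noise_sd,
#'   n_dup_genes, age_effect, sex_effect).
#' @param seed integer master seed; all data products derive their own
#'   streams from it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 1000L,
                             target_corr = default_target_corr(),
                             conc_means = c(GlycA = 1.30, AAT = 1.19,
                                            AGP = 789, HP = 1.09, TF = 2.65),
                             conc_sds = c(GlycA = 0.18, AAT = 0.20,
                                          AGP = 203, HP = 0.49, TF = 0.38),
                             n_nmr_features = 149L,
                             target_r2 = c(AAT = 0.43, AGP = 0.64,
                                           HP = 0.56, TF = 0.18),
                             block_size = 8L,
                             detection_limit_quantile = 0.01,
                             covariate_params = list(),
                             hazard_spec = default_hazard_spec(),
                             followup_years = 8,
                             retrospective_years = 10,
                             expression = list(),
                             seed = 1L) {
  stopifnot_msg(all(conc_sds > 0), "conc_sds must be positive")
  stopifnot_msg(followup_years > 0, "followup_years must be positive")
  stopifnot_msg(isTRUE(all.equal(target_corr, t(target_corr))),
                "target_corr must be symmetric")
  stopifnot_msg(all(abs(diag(target_corr) - 1) < 1e-12),
                "target_corr must have unit diagonal")
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("target_corr is not positive semi-definite (eigenvalue %.6g)",
                 min(ev)), call. = FALSE)
  }
  for (o in hazard_spec) {
    stopifnot_msg(o$baseline_rate >= 0, "baseline hazard must be non-negative")
  }
  codes <- vapply(hazard_spec, function(o) o$codes, "")
  stopifnot_msg(!anyDuplicated(codes), "hazard_spec outcomes must have distinct ICD-10 codes")

  cov_def <- list(age_range = c(25, 74), p_female = 0.5, p_smoking = 0.25,
                  bmi_mean = 27, bmi_sd = 4.7, sbp_mean = 137, sbp_sd = 17,
                  alcohol_mean = 35, alcohol_sd = 40, citrate_mean = 0.11,
                  citrate_sd = 0.02, albumin_mean = 45, albumin_sd = 2.5,
                  vldl_d_mean = 36.6, vldl_d_sd = 0.8, crp_mean = 1.8,
                  crp_sd = 3.2, crp_loading = 0.5, p_pregnant = 0.02)
  cov_def[names(covariate_params)] <- covariate_params

  expr_def <- list(n_samples = 518L, n_probes = 700L,
                   module_sizes = c(mod01 = 40L, mod02 = 30L, mod03 = 25L,
                                    mod04 = 20L, mod05 = 15L),
                   aat_assoc = c(mod01 = 0.23, mod02 = 0, mod03 = 0,
                                 mod04 = 0, mod05 = 0),
                   loading = 0.8, noise_sd = 0.6, n_dup_genes = 20L,
                   age_effect = 0, sex_effect = 0)
  expr_def[names(expression)] <- expression

  cfg <- list(n_samples = as.integer(n_samples), target_corr = target_corr,
              conc_means = conc_means, conc_sds = conc_sds,
              n_nmr_features = as.integer(n_nmr_features),
              target_r2 = target_r2, block_size = as.integer(block_size),
              detection_limit_quantile = detection_limit_quantile,
              covariate_params = cov_def, hazard_spec = hazard_spec,
              followup_years = followup_years,
              retrospective_years = retrospective_years,
              expression = expr_def, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Default outcome hazard specification
#'
#' A small registry of outcomes spanning single three-digit codes and code
#' ranges, with per-SD log hazard ratios on the standardised log biomarkers
#' mirroring the headline association sizes, plus a null outcome.
#'
#' @return named list of outcome specifications.
#' @export
default_hazard_spec <- function() {
  list(
    heart_failure = list(label = "Heart failure", codes = "I50",
                         baseline_rate = 0.004,
                         log_hr = c(AAT = log(1.6))),
    influenza_pneumonia = list(label = "Influenza and pneumonia",
                               codes = "J09-J18", baseline_rate = 0.005,
                               log_hr = c(AAT = log(1.37))),
    liver_disease = list(label = "Diseases of the liver", codes = "K70-K77",
                         baseline_rate = 0.002,
                         log_hr = c(AAT = log(1.81))),
    chronic_lower_respiratory = list(label = "Chronic lower respiratory diseases",
                                     codes = "J40-J47", baseline_rate = 0.004,
                                     log_hr = c(HP = log(1.36))),
    atherosclerosis = list(label = "Atherosclerosis", codes = "I70",
                           baseline_rate = 0.002,
                           log_hr = c(HP = log(1.67))),
    dorsalgia = list(label = "Dorsalgia", codes = "M54",
                     baseline_rate = 0.004, log_hr = c())
  )
}

# Moment inversion of the log-normal: given natural-scale mean m and SD s,
# the log-scale parameters are sdlog^2 = log(1 + s^2/m^2),
# meanlog = log(m) - sdlog^2/2.
lognormal_params <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Symmetric square root of a PSD correlation matrix (tolerating tiny
# negative eigenvalues from floating point only).
psd_root <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop(sprintf("correlation matrix is not positive semi-definite (eigenvalue %.6g)",
                 min(e$values)), call. = FALSE)
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate the glycoprotein/GlycA panel
#'
#' Draws multivariate log-normal concentrations whose log-scale correlations
#' target `config$target_corr` (Gaussian copula) and whose natural-scale
#' means and SDs match `conc_means`/`conc_sds` by moment inversion.
#'
#' @param config a [generator_config()].
#' @return data.frame with `id` and one natural-scale concentration column
#'   per analyte; attribute `z` holds the underlying standardised log values.
#' @export
generate_panel <- function(config) {
  n <- config$n_samples
  set.seed(child_seed(config$seed, 1L))
  Zraw <- matrix(stats::rnorm(n * 5L), n, 5L)
  Z <- Zraw %*% psd_root(config$target_corr)
  colnames(Z) <- ANALYTES
  panel <- data.frame(id = sprintf("P%06d", seq_len(n)))
  for (a in ANALYTES) {
    lp <- lognormal_params(config$conc_means[[a]], config$conc_sds[[a]])
    panel[[a]] <- exp(lp$meanlog + lp$sdlog * Z[, a])
  }
  attr(panel, "z") <- Z
  panel
}

# Default NMR loading structure: the first feature is the GlycA signal
# itself (loading 1 on log GlycA, small noise); each glycoprotein has a
# block of `block_size` features loading 1 on its standardised log value
# with block noise SD to be calibrated; remaining features are nuisance,
# driven by 10 shared latent factors and independent of the panel.
nmr_structure <- function(config) {
  p <- config$n_nmr_features
  k <- config$block_size
  stopifnot_msg(p >= 1L + 4L * k, "n_nmr_features too small for the block design")
  L <- matrix(0, p, 5L, dimnames = list(nmr_feature_names(p), ANALYTES))
  L[1L, "GlycA"] <- 1
  block_rows <- list()
  r <- 2L
  for (a in c("AAT", "AGP", "HP", "TF")) {
    rows <- r:(r + k - 1L)
    L[rows, a] <- 1
    block_rows[[a]] <- rows
    r <- r + k
  }
  nuisance <- r:p
  q <- 10L
  set.seed(child_seed(config$seed, 2L))
  G <- matrix(0, p, q)
  for (i in nuisance) {
    f <- sample.int(q, 2L)
    G[i, f] <- stats::runif(2L, 0.4, 0.9)
  }
  list(L = L, G = G, block_rows = block_rows, nuisance = nuisance)
}

# Population best-linear-predictor R^2 of each glycoprotein's standardised
# log value given all NMR log-scale features, for block noise SDs d.
nmr_population_r2 <- function(config, d, str = nmr_structure(config)) {
  p <- config$n_nmr_features
  noise <- rep(0.6, p)
  noise[1L] <- 0.05
  for (a in names(str$block_rows)) noise[str$block_rows[[a]]] <- d[[a]]
  C <- config$target_corr
  Sxx <- str$L %*% C %*% t(str$L) + str$G %*% t(str$G) + diag(noise^2)
  Sxz <- str$L %*% C
  sol <- solve(Sxx, Sxz)
  r2 <- colSums(Sxz * sol)
  names(r2) <- ANALYTES
  list(r2 = r2, noise = noise)
}

# Calibrate per-block noise SDs so the population R^2 for each glycoprotein
# equals config$target_r2. Solved by sweeps of univariate root-finds; the
# cross-coupling between blocks is weak so a few sweeps converge.
calibrate_nmr_noise <- function(config, str = nmr_structure(config)) {
  d <- c(AAT = 1, AGP = 1, HP = 1, TF = 1)
  for (sweep in 1:6) {
    for (a in names(d)) {
      target <- config$target_r2[[a]]
      f <- function(x) {
        dd <- d
        dd[[a]] <- x
        nmr_population_r2(config, dd, str)$r2[[a]] - target
      }
      lo <- 1e-3
      hi <- 200
      if (f(hi) > 0) {
        d[[a]] <- hi  # target below the floor set by other features
      } else if (f(lo) < 0) {
        stop(sprintf("target R^2 %.2f for %s is unattainable with this design",
                     target, a), call. = FALSE)
      } else {
        d[[a]] <- stats::uniroot(f, c(lo, hi), tol = 1e-7)$root
      }
    }
  }
  d
}

#' Generate the NMR feature matrix
#'
#' Log-scale features are linear in the panel's standardised log analytes
#' plus shared latent factors and independent noise; per-glycoprotein
#' feature-block noise is calibrated so the population R^2 of the best
#' linear predictor of each log glycoprotein equals `config$target_r2`
#' (0.43 for AAT by default). The lowest `detection_limit_quantile` fraction
#' of each feature is set to exactly zero, emulating detection limits.
#'
#' @param panel output of [generate_panel()] (or any data.frame carrying a
#'   `z` attribute of standardised log analytes).
#' @param config a [generator_config()].
#' @return samples x features numeric matrix of natural-scale concentrations
#'   with feature names; attributes `loading`, `noise_sd`, `block_noise`.
#' @export
generate_nmr <- function(panel, config) {
  Z <- attr(panel, "z")
  stopifnot_msg(!is.null(Z), "panel must carry its standardised log values (attribute 'z')")
  str <- nmr_structure(config)
  stopifnot_msg(nrow(str$L) == config$n_nmr_features,
                "loading matrix rows must equal n_nmr_features")
  d <- calibrate_nmr_noise(config, str)
  pop <- nmr_population_r2(config, d, str)
  n <- nrow(Z)
  p <- config$n_nmr_features
  set.seed(child_seed(config$seed, 3L))
  f <- matrix(stats::rnorm(n * ncol(str$G)), n, ncol(str$G))
  e <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% t(str$L) + f %*% t(str$G) + e %*% diag(pop$noise)
  # Natural scale: per-feature log-mean offsets for plausible concentrations;
  # the GlycA feature shares the panel GlycA's log-normal location.
  lm_means <- stats::runif(p, -2, 1.5)
  lp <- lognormal_params(config$conc_means[["GlycA"]], config$conc_sds[["GlycA"]])
  lm_means[1L] <- lp$meanlog
  conc <- exp(sweep(0.35 * X, 2, lm_means, "+"))
  conc[, 1L] <- exp(lp$meanlog + lp$sdlog * X[, 1L])
  colnames(conc) <- rownames(str$L)
  rownames(conc) <- panel$id
  n_zero <- floor(config$detection_limit_quantile * n)
  if (n_zero > 0) {
    for (j in seq_len(p)) {
      conc[order(conc[, j])[seq_len(n_zero)], j] <- 0
    }
  }
  attr(conc, "loading") <- str$L
  attr(conc, "noise_sd") <- pop$noise
  attr(conc, "block_noise") <- d
  attr(conc, "population_r2") <- pop$r2
  conc
}

#' Generate baseline covariates
#'
#' Age uniform over the cohort age range, sex coded 1 = men / 2 = women,
#' log-normal BMI, systolic blood pressure, alcohol consumption, citrate,
#' albumin and VLDL particle diameter, a smoking indicator, a pregnancy flag
#' for a small fraction of women, and CRP generated to correlate with the
#' glycoprotein burden (via the mean standardised log analyte).
#'
#' @param config a [generator_config()].
#' @param panel output of [generate_panel()]; supplies the glycoprotein
#'   signal CRP is correlated with.
#' @return data.frame of per-person covariates.
#' @export
generate_covariates <- function(config, panel) {
  cp <- config$covariate_params
  n <- config$n_samples
  Z <- attr(panel, "z")
  set.seed(child_seed(config$seed, 4L))
  sex <- ifelse(stats::runif(n) < cp$p_female, 2L, 1L)
  rln <- function(m, s) {
    lp <- lognormal_params(m, s)
    stats::rlnorm(n, lp$meanlog, lp$sdlog)
  }
  zbar <- scale(rowMeans(Z))[, 1L]
  crp_lp <- lognormal_params(cp$crp_mean, cp$crp_sd)
  crp <- exp(crp_lp$meanlog + crp_lp$sdlog *
               (cp$crp_loading * zbar +
                  sqrt(max(0, 1 - cp$crp_loading^2)) * stats::rnorm(n)))
  data.frame(
    id = panel$id,
    age = stats::runif(n, cp$age_range[1], cp$age_range[2]),
    sex = sex,
    bmi = rln(cp$bmi_mean, cp$bmi_sd),
    smoking = as.integer(stats::runif(n) < cp$p_smoking),
    sbp = rln(cp$sbp_mean, cp$sbp_sd),
    alcohol = rln(cp$alcohol_mean, cp$alcohol_sd),
    citrate = rln(cp$citrate_mean, cp$citrate_sd),
    albumin = rln(cp$albumin_mean, cp$albumin_sd),
    vldl_d = rln(cp$vldl_d_mean, cp$vldl_d_sd),
    crp = crp,
    pregnant = as.integer(sex == 2L & stats::runif(n) < cp$p_pregnant)
  )
}

#' Generate registry-style ICD-10 event records
#'
#' For each person and outcome, the hazard on the age timescale is
#' `baseline_rate * exp(sum(log_hr * z))` where `z` are the standardised log
#' biomarkers. The baseline hazard is constant in age (exponential), so
#' left truncation at the baseline age is exact by memorylessness; event
#' ages are drawn by inverse-CDF from a per-outcome uniform stream (doubling
#' a baseline rate with the same seed strictly grows the incident set).
#' Events landing within the follow-up window become incident-source
#' records; an independent draw over the retrospective window produces
#' pre-baseline (prevalent-source) records.
#'
#' @param panel output of [generate_panel()].
#' @param covariates output of [generate_covariates()].
#' @param config a [generator_config()].
#' @return data.frame of records: `id`, `event_age`, `icd10`, `source`
#'   ("main"/"side"); attribute `truth` holds per-outcome generative values.
#' @export
generate_events <- function(panel, covariates, config) {
  Z <- attr(panel, "z")
  n <- config$n_samples
  recs <- list()
  truth <- list()
  for (i in seq_along(config$hazard_spec)) {
    o <- config$hazard_spec[[i]]
    if (o$baseline_rate < 0) stop("negative baseline hazard", call. = FALSE)
    eta <- rep(0, n)
    for (b in names(o$log_hr)) eta <- eta + o$log_hr[[b]] * Z[, b]
    rate <- o$baseline_rate * exp(eta)
    set.seed(child_seed(config$seed, 100L + i))
    u_inc <- stats::runif(n)
    u_prev <- stats::runif(n)
    u_prev_age <- stats::runif(n)
    u_side <- stats::runif(n)
    u_code <- stats::runif(n)
    t_inc <- -log(u_inc) / rate
    inc <- is.finite(t_inc) & t_inc <= config$followup_years
    prev_p <- 1 - exp(-rate * config$retrospective_years)
    prev <- u_prev < prev_p
    # record four-character codes spread across the definition's range;
    # matching downstream is by three-digit prefix
    codes3 <- expand_code_spec(o$codes)
    full_code <- paste0(codes3[1L + floor(u_code * length(codes3))],
                        1L + floor(u_side * 9))
    if (any(inc)) {
      recs[[length(recs) + 1L]] <- data.frame(
        id = panel$id[inc],
        event_age = covariates$age[inc] + t_inc[inc],
        icd10 = full_code[inc],
        source = ifelse(u_side[inc] < 0.3, "side", "main"))
    }
    if (any(prev)) {
      recs[[length(recs) + 1L]] <- data.frame(
        id = panel$id[prev],
        event_age = pmax(0, covariates$age[prev] -
                           u_prev_age[prev] * config$retrospective_years),
        icd10 = full_code[prev],
        source = ifelse(u_side[prev] < 0.3, "side", "main"))
    }
    truth[[names(config$hazard_spec)[i]]] <-
      list(log_hr = o$log_hr, baseline_rate = o$baseline_rate,
           n_incident = sum(inc), n_prevalent = sum(prev))
  }
  # Non-outcome noise records (health checks) exercise non-matching codes.
  set.seed(child_seed(config$seed, 99L))
  noise_idx <- which(stats::runif(n) < 0.05)
  if (length(noise_idx) > 0) {
    recs[[length(recs) + 1L]] <- data.frame(
      id = panel$id[noise_idx],
      event_age = covariates$age[noise_idx] +
        stats::runif(length(noise_idx), 0, config$followup_years),
      icd10 = "Z001", source = "main")
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$id, out$event_age), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Generate modular gene expression data with an AAT-linked module
#'
#' Each module's probes share a latent profile scaled by a loading plus
#' independent noise; background probes are pure noise. A configurable
#' subset of latent profiles correlates with a standardised log-AAT vector
#' (`aat_assoc`; by default module `mod01` at 0.23, so regressing AAT on its
#' eigengene recovers beta = 0.23). Some genes carry duplicate probes to
#' exercise probe collapsing.
#'
#' @param config a [generator_config()]; see the `expression` block.
#' @return list with `expr` (probes x samples log2-scale matrix), `annot`
#'   (probe -> gene data.frame), `modules` (named list of probe id vectors),
#'   `aat` (standardised log AAT vector), `age`, `sex`, and `truth`.
#' @export
generate_expression <- function(config) {
  e <- config$expression
  n <- e$n_samples
  p <- e$n_probes
  stopifnot_msg(all(e$module_sizes >= 2L), "module sizes must be >= 2")
  stopifnot_msg(sum(e$module_sizes) <= p,
                "modules larger than the probe universe")
  set.seed(child_seed(config$seed, 5L))
  aat <- stats::rnorm(n)
  age <- stats::runif(n, 25, 74)
  sex <- sample(1:2, n, replace = TRUE)
  probes <- sprintf("probe_%04d", seq_len(p))
  n_main_genes <- p - e$n_dup_genes
  genes <- sprintf("GENE%04d", seq_len(n_main_genes))
  gene_of <- c(genes, genes[seq_len(e$n_dup_genes)])  # last probes duplicate early genes
  annot <- data.frame(probe = probes, gene = gene_of[seq_len(p)])
  expr <- matrix(stats::rnorm(p * n, mean = 7, sd = 1), p, n,
                 dimnames = list(probes, sprintf("S%04d", seq_len(n))))
  modules <- list()
  latents <- list()
  idx <- 1L
  for (m in names(e$module_sizes)) {
    sz <- e$module_sizes[[m]]
    rows <- idx:(idx + sz - 1L)
    idx <- idx + sz
    rho <- e$aat_assoc[[m]]
    latent <- rho * aat + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    latent <- latent + e$age_effect * scale(age)[, 1L] +
      e$sex_effect * (sex - 1.5)
    expr[rows, ] <- 7 + e$loading * matrix(latent, sz, n, byrow = TRUE) +
      matrix(stats::rnorm(sz * n, sd = e$noise_sd), sz, n)
    modules[[m]] <- probes[rows]
    latents[[m]] <- latent
  }
  list(expr = expr, annot = annot, modules = modules, aat = aat,
       age = age, sex = sex,
       truth = list(latents = latents, aat_assoc = e$aat_assoc,
                    loading = e$loading))
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper drawing the glycoprotein panel, NMR feature matrix,
#' covariates and event records under one configuration; all components
#' share person ids and `truth` records every generative quantity.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort`: list with `panel`, `nmr`,
#'   `covariates`, `records`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  panel <- generate_panel(config)
  nmr <- generate_nmr(panel, config)
  covariates <- generate_covariates(config, panel)
  records <- generate_events(panel, covariates, config)
  out <- list(panel = panel, nmr = nmr, covariates = covariates,
              records = records,
              truth = list(z = attr(panel, "z"),
                           loading = attr(nmr, "loading"),
                           noise_sd = attr(nmr, "noise_sd"),
                           population_r2 = attr(nmr, "population_r2"),
                           outcomes = attr(records, "truth")),
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort's components as CSV files
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, "panel.csv"),
             nmr = file.path(dir, "nmr.csv"),
             covariates = file.path(dir, "covariates.csv"),
             records = file.path(dir, "records.csv"))
  utils::write.csv(cohort$panel, paths["panel"], row.names = FALSE)
  nmr_df <- data.frame(id = rownames(cohort$nmr), cohort$nmr,
                       check.names = FALSE)
  utils::write.csv(nmr_df, paths["nmr"], row.names = FALSE)
  utils::write.csv(cohort$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(cohort$records, paths["records"], row.names = FALSE)
  invisible(paths)
}
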