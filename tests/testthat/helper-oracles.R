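# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and glmnet) so equality checks are meaningful.

# Plain cyclic coordinate-descent lasso with intercept, minimising
# 1/(2n) ||y - b0 - X b||^2 + lambda ||b||_1 (the same objective glmnet
# uses for gaussian with standardize = FALSE).
cd_lasso <- function(X, y, lambda, tol = 1e-13, max_iter = 200000L) {
  n <- nrow(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  yc <- y - mean(y)
  p <- ncol(X)
  b <- rep(0, p)
  xss <- colMeans(Xc^2)
  r <- yc
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xss[j] == 0) next
      rho <- mean(Xc[, j] * r) + xss[j] * b[j]
      bj <- soft(rho, lambda) / xss[j]
      if (bj != b[j]) {
        r <- r - Xc[, j] * (bj - b[j])
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol) break
  }
  c(`(Intercept)` = mean(y) - sum(xm * b), stats::setNames(b, colnames(X)))
}

# Brute-force 10-fold CV oracle: refit per (fold, lambda) with cd_lasso
# given a fixed fold assignment and grid; returns the per-fold MSE matrix
# on the standardised log target.
cv_oracle <- function(X, target, fold_id, grid) {
  ly <- log(target)
  z <- (ly - mean(ly)) / stats::sd(ly)
  k <- max(fold_id)
  mse <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    test <- fold_id == f
    for (l in seq_along(grid)) {
      co <- cd_lasso(X[!test, , drop = FALSE], z[!test], grid[l])
      pred <- co[1] + X[test, , drop = FALSE] %*% co[-1]
      mse[f, l] <- mean((pred - z[test])^2)
    }
  }
  mse
}

# Brute-force scan of the one-standard-error rule over a descending grid.
one_se_oracle <- function(lambda, mean_mse, se_mse) {
  i_min <- which.min(mean_mse)
  thr <- mean_mse[i_min] + se_mse[i_min]
  best <- NA_integer_
  for (i in seq_along(lambda)) {   # descending: first hit is the largest
    if (mean_mse[i] <= thr) {
      best <- i
      break
    }
  }
  lambda[best]
}

# Exhaustive enumeration oracle for incident/prevalent aggregation.
aggregate_oracle <- function(records, definitions, baseline, followup = 8) {
  codes_of <- lapply(definitions, glycadecomp::expand_code_spec)
  res <- list()
  for (o in names(definitions)) {
    for (i in seq_len(nrow(baseline))) {
      pid <- baseline$id[i]
      b <- baseline$baseline_age[i]
      ages <- records$event_age[records$id == pid &
                                  substr(records$icd10, 1, 3) %in% codes_of[[o]]]
      inc_ages <- ages[ages > b & ages <= b + followup]
      res[[length(res) + 1L]] <- data.frame(
        id = pid, outcome = o,
        prevalent = as.integer(any(ages <= b)),
        incident = as.integer(length(inc_ages) > 0),
        event_age = if (length(inc_ages) > 0) min(inc_ages) else NA_real_)
    }
  }
  do.call(rbind, res)
}

# Literal running-sum walk, written independently (loop form).
es_oracle <- function(genes_ranked, r_ranked, gene_set) {
  N <- length(genes_ranked)
  s <- 0
  best <- -Inf
  worst <- Inf
  for (i in seq_len(N)) {
    if (genes_ranked[i] %in% gene_set) s <- s + r_ranked[i] else s <- s - 1 / N
    best <- max(best, s)
    worst <- min(worst, s)
  }
  list(es = best, es_min = worst)
}

# All permutations of 1..n (for exhaustive GSEA enumeration).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n, factorial(n))
  col <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      rest <- seq_len(n)[-i]
      out[, col] <- c(i, rest[sub[, j]])
      col <- col + 1L
    }
  }
  out
}

# Small complete synthetic inputs for the risk scan (panel + covariates +
# events only; NMR omitted), returned in run_risk_scan cohort form with the
# true standardised log biomarkers as the analysed values.
make_scan_cohort <- function(n, seed, retrospective = 10,
                             hazard_spec = NULL, biomarkers = c("AAT", "HP", "GlycA")) {
  args <- list(n_samples = n, seed = seed, retrospective_years = retrospective)
  if (!is.null(hazard_spec)) args$hazard_spec <- hazard_spec
  cfg <- do.call(glycadecomp::generator_config, args)
  panel <- glycadecomp::generate_panel(cfg)
  cov <- glycadecomp::generate_covariates(cfg, panel)
  rec <- glycadecomp::generate_events(panel, cov, cfg)
  defs <- stats::setNames(lapply(cfg$hazard_spec, `[[`, "codes"),
                          names(cfg$hazard_spec))
  baseline <- data.frame(id = cov$id, baseline_age = cov$age)
  tab <- glycadecomp::aggregate_outcomes(rec, defs, baseline,
                                         followup_years = cfg$followup_years)
  bm <- data.frame(id = panel$id)
  for (b in biomarkers) bm[[b]] <- log(panel[[b]])
  list(covariates = glycadecomp::prepare_cox_covariates(cov),
       outcomes = tab, biomarkers = bm, config = cfg, records = rec,
       panel = panel)
}
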