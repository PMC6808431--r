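# Sparse (lasso) imputation models for glycoprotein concentrations from NMR
# features + age, sex, BMI: 10-fold cross-validated lambda tuning with the
# one-standard-error rule, final fit, evaluation, serialisation, and
# application with validity-range QC. Fitting is delegated to glmnet (the
# field-standard coordinate-descent solver); the grid construction, fold
# bookkeeping, 1-SE selection and both coefficient conventions are owned
# here.

#' Construct the lasso penalty grid
#'
#' 100 log-spaced values from the smallest penalty that zeroes every slope
#' (`max |x_j' (y - ybar)| / n` on the centred data) down to `ratio` times
#' that value, in descending order.
#'
#' @param X design matrix (samples x predictors).
#' @param y response vector.
#' @param n_lambda grid length.
#' @param ratio smallest/largest penalty ratio.
#' @return descending numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, n_lambda = 100L, ratio = 1e-4) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xc, yc))) / length(y)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# Spearman correlation with a 0 convention for constant predictions (at
# penalties above lambda_max every prediction is the intercept).
spearman0 <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  stats::cor(pred, obs, method = "spearman")
}

#' Cross-validated lasso training for one glycoprotein
#'
#' The natural-scale target is log transformed and standardised; for each of
#' `n_lambda` penalties a lasso is fit on each 9/10ths of the samples and
#' test-fold MSE and Spearman correlation are computed between predicted and
#' observed log-standardised target. Folds are a seeded random permutation
#' with sizes differing by at most one.
#'
#' @param features complete numeric design matrix (log-standardised NMR
#'   features, standardised age, sex coded 1/2, log-standardised BMI).
#' @param target positive natural-scale concentrations.
#' @param n_folds,n_lambda,lambda_min_ratio CV folds and penalty grid shape.
#' @param seed fold-assignment seed (recorded in the report).
#' @return object of class `cv_report`: penalty grid, fold assignment,
#'   per-fold MSE and Spearman matrices, their means/SEs, and the indices of
#'   the minimum-MSE and 1-SE penalties.
#' @export
cv_train <- function(features, target, n_folds = 10L, n_lambda = 100L,
                     lambda_min_ratio = 1e-4, seed = 1L) {
  stopifnot_msg(is.matrix(features) && !anyNA(features),
                "features must be a complete numeric matrix")
  stopifnot_msg(all(target > 0), "target concentrations must be positive")
  n <- nrow(features)
  stopifnot_msg(n_folds <= n, "n_folds exceeds the sample size")
  ly <- log(target)
  m_y <- mean(ly)
  s_y <- stats::sd(ly)
  stopifnot_msg(s_y > 0, "target is constant")
  z <- (ly - m_y) / s_y
  grid <- lambda_grid(features, z, n_lambda, lambda_min_ratio)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(n_folds), length.out = n))
  mse <- matrix(NA_real_, n_folds, n_lambda)
  rho <- matrix(NA_real_, n_folds, n_lambda)
  for (k in seq_len(n_folds)) {
    test <- fold_id == k
    fit <- glmnet::glmnet(features[!test, , drop = FALSE], z[!test],
                          family = "gaussian", lambda = grid,
                          standardize = FALSE, thresh = 1e-11)
    pred <- stats::predict(fit, features[test, , drop = FALSE])
    # glmnet may stop early on the path; keep the grid positions it fit
    fitted_cols <- match(signif(fit$lambda, 10), signif(grid, 10))
    obs <- z[test]
    for (l in seq_along(fitted_cols)) {
      j <- fitted_cols[l]
      mse[k, j] <- mean((pred[, l] - obs)^2)
      rho[k, j] <- spearman0(pred[, l], obs)
    }
  }
  keep <- which(colSums(is.na(mse)) == 0)
  grid <- grid[keep]
  mse <- mse[, keep, drop = FALSE]
  rho <- rho[, keep, drop = FALSE]
  mean_mse <- colMeans(mse)
  se_mse <- apply(mse, 2, stats::sd) / sqrt(n_folds)
  report <- list(lambda = grid, fold_id = fold_id, mse = mse, rho = rho,
                 mean_mse = mean_mse, se_mse = se_mse,
                 mean_rho = colMeans(rho), sd_rho = apply(rho, 2, stats::sd),
                 idx_min = which.min(mean_mse), seed = seed,
                 target_meanlog = m_y, target_sdlog = s_y)
  class(report) <- "cv_report"
  report$idx_1se <- attr(select_lambda_1se(report), "index")
  report
}

#' One-standard-error penalty selection
#'
#' Returns the largest penalty whose mean cross-validated MSE is within one
#' standard error of the smallest mean MSE (the SE being that of the
#' minimising penalty). The grid is descending, so this is the left-most
#' qualifying grid position; ties resolve toward the larger penalty
#' (sparser model) by construction.
#'
#' @param report a `cv_report`.
#' @return the selected penalty, with the grid index as attribute `index`.
#' @export
select_lambda_1se <- function(report) {
  threshold <- report$mean_mse[report$idx_min] + report$se_mse[report$idx_min]
  idx <- which(report$mean_mse <= threshold)[1L]
  structure(report$lambda[idx], index = idx)
}

# L1-penalised least-squares fit at one penalty via the glmnet path (warm
# starts down the grid for numerical agreement with path-wise solvers).
lasso_at <- function(X, y, lambda, grid = NULL, thresh = 1e-13) {
  if (is.null(grid)) grid <- lambda_grid(X, y)
  path <- sort(unique(c(grid[grid > lambda], lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = path,
                        standardize = FALSE, thresh = thresh)
  co <- stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y)
  stats::setNames(as.numeric(co), rownames(co))
}

#' Fit the final imputation model at a chosen penalty
#'
#' Fits the lasso on the full training data at `lambda` and stores both
#' coefficient conventions: standardised (inputs as supplied to training)
#' and raw (log-scale inputs, age in years, sex coded 1/2), obtained by
#' back-transforming through the stored standardisation parameters. The
#' model predicts the natural-log concentration; exponentiate to obtain
#' the concentration in the analyte's printed unit.
#'
#' @param features design matrix as in [cv_train()].
#' @param target positive natural-scale concentrations.
#' @param lambda penalty (e.g. from [select_lambda_1se()]).
#' @param preprocess the `params` list from [log_standardize()] used to
#'   build `features`; required to express raw-scale coefficients.
#' @param analyte,unit target name and unit for bookkeeping.
#' @param validity_range natural-scale c(min, max) of acceptable imputed
#'   values (assay range), or NULL for no range check.
#' @param cv optional `cv_report` whose mean Spearman is carried for
#'   overfitting assessment.
#' @return object of class `imputation_model`.
#' @export
fit_final <- function(features, target, lambda, preprocess = NULL,
                      analyte = "analyte", unit = "mg/L",
                      validity_range = NULL, cv = NULL) {
  stopifnot_msg(lambda >= 0, "lambda must be non-negative")
  ly <- log(target)
  m_y <- mean(ly)
  s_y <- stats::sd(ly)
  z <- (ly - m_y) / s_y
  co <- lasso_at(features, z, lambda)
  intercept <- unname(co[1L])
  beta <- co[-1L]
  coef_raw <- NULL
  if (!is.null(preprocess)) {
    # standardised prediction: z = a + sum_j b_j (v_j - mu_j)/sd_j where v_j
    # is the log feature (or raw age); log y = m_y + s_y * z, so the raw
    # coefficient on v_j is s_y b_j / sd_j and the intercept absorbs means.
    raw_int <- m_y + s_y * intercept
    coef_raw <- numeric(0)
    for (j in names(beta)) {
      b <- beta[[j]]
      if (b == 0) next
      if (j %in% preprocess$passthrough) {
        coef_raw[[j]] <- s_y * b
      } else {
        coef_raw[[j]] <- s_y * b / preprocess$sd[[j]]
        raw_int <- raw_int - coef_raw[[j]] * preprocess$mean[[j]]
      }
    }
    coef_raw <- c("(Intercept)" = raw_int, coef_raw)
  }
  model <- list(analyte = analyte, unit = unit, lambda = lambda,
                intercept = intercept, coef_std = beta[beta != 0],
                coef_raw = coef_raw, preprocess = preprocess,
                target_meanlog = m_y, target_sdlog = s_y,
                validity_range = validity_range,
                n_features = sum(beta != 0),
                cv_mean_rho = if (!is.null(cv)) cv$mean_rho[cv$idx_1se] else NA_real_,
                cv_sd_rho = if (!is.null(cv)) cv$sd_rho[cv$idx_1se] else NA_real_)
  class(model) <- "imputation_model"
  model
}

# Linear predictor on the standardised design (training convention).
predict_std <- function(model, features) {
  b <- model$coef_std
  if (length(b) == 0) return(rep(model$intercept, nrow(features)))
  missing_cols <- setdiff(names(b), colnames(features))
  stopifnot_msg(length(missing_cols) == 0,
                paste("features lack model inputs:",
                      paste(missing_cols, collapse = ", ")))
  drop(model$intercept + features[, names(b), drop = FALSE] %*% b)
}

#' Evaluate an imputation model against observed concentrations
#'
#' @param model an `imputation_model`.
#' @param features standardised design matrix (training convention).
#' @param target positive observed natural-scale concentrations.
#' @return list with `rho` (in-sample Spearman), `r2` (squared Pearson of
#'   predicted vs observed log-standardised values), `cv_mean_rho` and
#'   `overfit_gap` (in-sample minus CV-mean Spearman).
#' @export
evaluate <- function(model, features, target) {
  stopifnot_msg(nrow(features) == length(target), "mismatched ids")
  stopifnot_msg(length(target) >= 3, "need at least 3 paired observations")
  pred <- predict_std(model, features)
  obs <- (log(target) - model$target_meanlog) / model$target_sdlog
  rho <- spearman0(pred, obs)
  r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, obs)^2
  list(rho = rho, r2 = r2, cv_mean_rho = model$cv_mean_rho,
       overfit_gap = rho - model$cv_mean_rho)
}

#' Impute concentrations in a new cohort with QC flags
#'
#' Uses the raw-scale model form (natural-log inputs, age in years, sex
#' coded 1/2), avoiding cohort-dependent re-standardisation. Samples with
#' any missing model input get a missing value flagged "incomplete-inputs";
#' imputed concentrations outside the assay validity range get a missing
#' value flagged "out-of-range".
#'
#' @param model an `imputation_model` with raw coefficients.
#' @param data data.frame or matrix of natural-scale inputs with named
#'   columns covering the model's selected inputs (NMR features as
#'   concentrations, `age` in years, `sex` coded 1/2, `bmi` natural scale).
#' @param log_inputs names of columns entering on the log scale (defaults to
#'   every model input except `age` and `sex`).
#' @return data.frame with `value` (imputed concentration, NA when flagged)
#'   and `flag` ("ok", "incomplete-inputs", "out-of-range"); summary counts
#'   in attribute `counts`.
#' @export
apply_model <- function(model, data, log_inputs = NULL) {
  stopifnot_msg(!is.null(model$coef_raw), "model lacks raw-scale coefficients")
  co <- model$coef_raw
  inputs <- setdiff(names(co), "(Intercept)")
  data <- as.data.frame(data, check.names = FALSE)
  missing_cols <- setdiff(inputs, colnames(data))
  stopifnot_msg(length(missing_cols) == 0,
                paste("data lacks model inputs:", paste(missing_cols, collapse = ", ")))
  if (is.null(log_inputs)) log_inputs <- setdiff(inputs, c("age", "sex"))
  n <- nrow(data)
  X <- matrix(NA_real_, n, length(inputs), dimnames = list(NULL, inputs))
  for (j in inputs) {
    v <- as.numeric(data[[j]])
    if (j %in% log_inputs) {
      v[!is.na(v) & v <= 0] <- NA  # unlogged zeros cannot enter; treat as missing
      v <- log(v)
    }
    X[, j] <- v
  }
  incomplete <- if (length(inputs) == 0) rep(FALSE, n) else !stats::complete.cases(X)
  pred <- rep(NA_real_, n)
  ok_rows <- !incomplete
  pred[ok_rows] <- if (length(inputs) == 0) co[["(Intercept)"]] else
    co[["(Intercept)"]] + X[ok_rows, , drop = FALSE] %*% co[inputs]
  value <- exp(pred)
  flag <- rep("ok", n)
  flag[incomplete] <- "incomplete-inputs"
  if (!is.null(model$validity_range)) {
    oor <- !incomplete & (value < model$validity_range[1] |
                            value > model$validity_range[2])
    flag[oor] <- "out-of-range"
    value[oor] <- NA_real_
  }
  value[incomplete] <- NA_real_
  out <- data.frame(value = value, flag = flag)
  if (!is.null(rownames(data))) rownames(out) <- rownames(data)
  attr(out, "counts") <- table(factor(flag, levels = c("ok", "incomplete-inputs",
                                                       "out-of-range")))
  out
}

#' Train one glycoprotein imputation model end to end
#'
#' Convenience wrapper: cross-validated tuning, 1-SE penalty selection,
#' final fit, and in-sample evaluation.
#'
#' @inheritParams cv_train
#' @inheritParams fit_final
#' @return list with `model`, `cv`, `lambda`, `metrics`.
#' @export
train_imputation_model <- function(features, target, preprocess = NULL,
                                   analyte = "analyte", unit = "mg/L",
                                   validity_range = NULL, n_folds = 10L,
                                   n_lambda = 100L, seed = 1L) {
  cv <- cv_train(features, target, n_folds = n_folds, n_lambda = n_lambda,
                 seed = seed)
  lam <- select_lambda_1se(cv)
  model <- fit_final(features, target, as.numeric(lam), preprocess = preprocess,
                     analyte = analyte, unit = unit,
                     validity_range = validity_range, cv = cv)
  list(model = model, cv = cv, lambda = as.numeric(lam),
       metrics = evaluate(model, features, target))
}

#' Serialise an imputation model to JSON
#'
#' Stores both coefficient conventions, the preprocessing parameters, the
#' penalty and the validity range at full precision; [read_imputation_model()]
#' reproduces predictions exactly.
#'
#' @param model an `imputation_model`.
#' @param path output file.
#' @export
write_imputation_model <- function(model, path) {
  obj <- unclass(model)
  obj$coef_std <- as.list(obj$coef_std)
  obj$coef_raw <- as.list(obj$coef_raw)
  if (!is.null(obj$preprocess)) {
    obj$preprocess$mean <- as.list(obj$preprocess$mean)
    obj$preprocess$sd <- as.list(obj$preprocess$sd)
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_imputation_model
#' @export
read_imputation_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$coef_std <- unlist(obj$coef_std)
  obj$coef_raw <- unlist(obj$coef_raw)
  if (!is.null(obj$preprocess)) {
    obj$preprocess$mean <- unlist(obj$preprocess$mean)
    obj$preprocess$sd <- unlist(obj$preprocess$sd)
    obj$preprocess$no_log <- as.character(obj$preprocess$no_log)
    obj$preprocess$passthrough <- as.character(obj$preprocess$passthrough)
  }
  if (!is.null(obj$validity_range)) obj$validity_range <- as.numeric(obj$validity_range)
  class(obj) <- "imputation_model"
  obj
}
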