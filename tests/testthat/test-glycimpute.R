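fixture_xy <- function(n, p, seed, beta = NULL, snr = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", seq_len(p))))
  if (is.null(beta)) beta <- rep(0, p)
  eta <- drop(X %*% beta)
  noise_sd <- if (all(beta == 0)) 1 else sqrt(var(eta) / snr)
  y <- exp(0.1 * scale(eta + rnorm(n, sd = noise_sd))[, 1])  # positive target
  list(X = X, y = y)
}

test_that("penalty grid has the configured shape", {
  f <- fixture_xy(80, 6, 1, beta = c(1, -1, rep(0, 4)))
  g <- lambda_grid(f$X, log(f$y))
  expect_length(g, 100L)
  expect_true(all(diff(g) < 0))
  expect_equal(g[100] / g[1], 1e-4, tolerance = 1e-10)
})

test_that("per-fold CV errors equal an explicit fold-loop refit oracle", {
  f <- fixture_xy(50, 5, 1, beta = c(1.2, -0.8, 0.5, 0, 0))
  rep <- cv_train(f$X, f$y, n_folds = 5, n_lambda = 25, seed = 1)
  oracle <- cv_oracle(f$X, f$y, rep$fold_id, rep$lambda)
  expect_equal(rep$mse, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("cross-validation is honest under the null and errors on bad input", {
  f <- fixture_xy(500, 8, 2)                     # target independent of X
  rep <- cv_train(f$X, f$y, seed = 3)
  expect_lt(abs(rep$mean_rho[rep$idx_1se]), 0.1)
  expect_error(cv_train(f$X[1:5, ], f$y[1:5], n_folds = 10), "n_folds")
  expect_error(cv_train(f$X, rep(2, 500)), "constant")
})

test_that("the one-standard-error rule matches a brute-force scan", {
  mk_report <- function(lambda, mean_mse, se_mse) {
    structure(list(lambda = lambda, mean_mse = mean_mse, se_mse = se_mse,
                   idx_min = which.min(mean_mse)), class = "cv_report")
  }
  # worked example: descending grid, min 3 with SE 0.1 -> largest lambda
  # with mean <= 3.1 is the 3.05 position
  r <- mk_report(c(5, 4, 3, 2, 1), c(3.5, 3.05, 3, 4, 5), c(0.1, 0.1, 0.1, 0.1, 0.1))
  expect_equal(as.numeric(select_lambda_1se(r)), 4)
  expect_equal(attr(select_lambda_1se(r), "index"), 2L)
  # all means identical -> largest lambda in the grid
  r2 <- mk_report(c(5, 4, 3), rep(2, 3), rep(0.5, 3))
  expect_equal(as.numeric(select_lambda_1se(r2)), 5)
  # zero SE at the minimum collapses the band to the minimiser
  r3 <- mk_report(c(5, 4, 3), c(3, 2, 2.5), c(0, 0, 0))
  expect_equal(as.numeric(select_lambda_1se(r3)), 4)
  # property: brute-force scan agrees on random reports
  for (s in 1:20) {
    set.seed(s)
    lam <- sort(exp(rnorm(30)), decreasing = TRUE)
    mm <- runif(30, 1, 2)
    se <- runif(30, 0, 0.2)
    r4 <- mk_report(lam, mm, se)
    expect_equal(as.numeric(select_lambda_1se(r4)), one_se_oracle(lam, mm, se))
  }
})

test_that("lasso coefficients match a coordinate-descent oracle to 1e-6", {
  for (s in 1:20) {
    f <- fixture_xy(60, 8, s, beta = c(rnorm(3), rep(0, 5)))
    z <- scale(log(f$y))[, 1]
    grid <- lambda_grid(f$X, z, n_lambda = 20)
    for (lam in grid[c(4, 10, 16)]) {
      ours <- glycadecomp:::lasso_at(f$X, z, lam, grid = grid)
      oracle <- cd_lasso(f$X, z, lam)
      expect_equal(ours, oracle, tolerance = 1e-6)
    }
  }
})

test_that("the fitted path is monotone in sparsity and has the shrinkage limits", {
  f <- fixture_xy(120, 10, 4, beta = c(1, -1, 0.5, rep(0, 7)))
  z <- scale(log(f$y))[, 1]
  grid <- lambda_grid(f$X, z, n_lambda = 40)
  fit <- glmnet::glmnet(f$X, z, lambda = grid, standardize = FALSE)
  nz <- colSums(as.matrix(fit$beta) != 0)
  expect_true(all(diff(nz) >= 0))   # grid descending: support only grows
  # lambda beyond lambda_max: all slopes zero, intercept = mean(z) = 0
  big <- fit_final(f$X, f$y, lambda = grid[1] * 2)
  expect_length(big$coef_std, 0)
  expect_equal(big$intercept, 0, tolerance = 1e-10)
  # lambda = 0 on a well-posed design reproduces OLS
  ols <- fit_final(f$X, f$y, lambda = 0)
  ref <- coef(lm(z ~ f$X))
  expect_equal(unname(ols$coef_std[paste0("v", 1:10)]), unname(ref[-1]),
               tolerance = 1e-6)
})

test_that("the 1-SE model recovers a planted sparse support", {
  hits <- 0L
  for (s in 1:100) {
    beta <- c(1, -1, 0.7, rep(0, 17))
    f <- fixture_xy(600, 20, 1000 + s, beta = beta, snr = 5)
    tr <- train_imputation_model(f$X, f$y, seed = s, n_lambda = 50)
    sel <- names(tr$model$coef_std)
    if (all(c("v1", "v2", "v3") %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("evaluation metrics behave at the extremes", {
  f <- fixture_xy(100, 4, 9, beta = c(2, 0, 0, 0), snr = 100)
  tr <- train_imputation_model(f$X, f$y, seed = 2)
  ev <- evaluate(tr$model, f$X, f$y)
  expect_gt(ev$rho, 0.9)
  expect_true(ev$r2 >= 0 && ev$r2 <= 1)
  # a perfect model: predictions identical to observations
  obs_z <- scale(log(f$y))[, 1]
  mock <- structure(list(intercept = 0,
                         coef_std = c(obs = 1),
                         target_meanlog = mean(log(f$y)),
                         target_sdlog = sd(log(f$y)),
                         cv_mean_rho = 0.9), class = "imputation_model")
  feats <- cbind(obs = obs_z)
  ev2 <- evaluate(mock, feats, f$y)
  expect_equal(ev2$rho, 1)
  expect_equal(ev2$r2, 1)
  expect_equal(ev2$overfit_gap, 0.1)
  # anti-correlated predictions: r^2 is sign-blind, rho is not
  mock$coef_std <- c(obs = -1)
  ev3 <- evaluate(mock, feats, f$y)
  expect_equal(ev3$rho, -1)
  expect_equal(ev3$r2, 1)
  expect_error(evaluate(mock, feats[1:2, , drop = FALSE], f$y[1:2]), "3")
})

test_that("imputation applies the raw-scale model with QC flags", {
  # intercept-only model imputes exp(intercept) everywhere
  m <- structure(list(analyte = "AAT", unit = "mg/L",
                      coef_raw = c(`(Intercept)` = log(1.2)),
                      validity_range = c(0.64, 2.58)),
                 class = "imputation_model")
  out <- apply_model(m, data.frame(x = 1:3))
  expect_equal(out$value, rep(1.2, 3))
  expect_equal(out$flag, rep("ok", 3))
  # below the AAT assay floor of 0.64 mg/L -> excluded
  m$coef_raw <- c(`(Intercept)` = log(0.50))
  out2 <- apply_model(m, data.frame(x = 1:3))
  expect_true(all(is.na(out2$value)))
  expect_equal(out2$flag, rep("out-of-range", 3))
  # missing model input -> missing output with its own flag
  m$coef_raw <- c(`(Intercept)` = 0, Glc = 0.2)
  dat <- data.frame(Glc = c(1.1, NA, 0.9))
  out3 <- apply_model(m, dat)
  expect_equal(out3$flag, c("ok", "incomplete-inputs", "ok"))
  expect_true(is.na(out3$value[2]))
  expect_equal(attr(out3, "counts")[["incomplete-inputs"]], 1L)
  expect_error(apply_model(m, data.frame(z = 1)), "lacks")
})

test_that("serialised models reload with identical predictions", {
  f <- fixture_xy(200, 6, 12, beta = c(1, -0.5, rep(0, 4)))
  colnames(f$X) <- c(paste0("feat", 1:4), "age", "sex")
  prep <- list(mean = c(feat1 = 0.1, feat2 = -0.2, feat3 = 0, feat4 = 0.3, age = 50),
               sd = c(feat1 = 1.1, feat2 = 0.9, feat3 = 1, feat4 = 1.2, age = 14),
               no_log = "age", passthrough = "sex")
  tr <- train_imputation_model(f$X, f$y, preprocess = prep, analyte = "AAT",
                               validity_range = c(0.5, 2), seed = 5)
  path <- tempfile(fileext = ".json")
  write_imputation_model(tr$model, path)
  back <- read_imputation_model(path)
  newdat <- data.frame(feat1 = exp(rnorm(20)), feat2 = exp(rnorm(20)),
                       feat3 = exp(rnorm(20)), feat4 = exp(rnorm(20)),
                       age = runif(20, 25, 74), sex = rep(1:2, 10))
  a <- apply_model(tr$model, newdat)
  b <- apply_model(back, newdat)
  expect_equal(b$value, a$value, tolerance = 1e-12)
  expect_identical(b$flag, a$flag)
})

test_that("imputation accuracy on calibrated synthetic data hits the design target", {
  cfg <- generator_config(n_samples = 4000, seed = 31)
  panel <- generate_panel(cfg)
  nmr <- generate_nmr(panel, cfg)
  cov <- generate_covariates(cfg, panel)
  rz <- replace_zeros(nmr)
  ds <- glycadecomp:::build_design(rz$matrix, cov)
  tr <- train_imputation_model(ds$matrix, panel$AAT, preprocess = ds$params,
                               analyte = "AAT", seed = 1)
  expect_equal(tr$metrics$r2, 0.43, tolerance = 0.07)
  expect_equal(tr$model$cv_mean_rho, 0.63, tolerance = 0.07)
})
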