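test_that("probe collapsing takes the per-sample maximum within genes", {
  expr <- matrix(c(3, 5, 1,
                   5, 2, 4,
                   0, 1, 2), 3, 3, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2", "s3")))
  annot <- data.frame(probe = c("p1", "p2", "p3"), gene = c("g1", "g1", "g2"))
  out <- collapse_probes(expr, annot)
  expect_equal(out["g1", ], c(s1 = 5, s2 = 5, s3 = 4))   # max rule per sample
  expect_equal(out["g2", ], expr["p3", ])                 # single probe copied
  # 14 probes over 10 genes: row count and every cell equal brute force
  set.seed(3)
  expr2 <- matrix(rnorm(14 * 6), 14, 6,
                  dimnames = list(sprintf("q%02d", 1:14), paste0("s", 1:6)))
  annot2 <- data.frame(probe = rownames(expr2),
                       gene = paste0("G", c(1:10, 1, 2, 3, 4)))
  out2 <- collapse_probes(expr2, annot2)
  expect_equal(nrow(out2), 10L)
  for (g in rownames(out2)) {
    rows <- annot2$probe[annot2$gene == g]
    expect_equal(out2[g, ], apply(expr2[rows, , drop = FALSE], 2, max))
  }
  # unannotated probes are dropped and counted
  annot3 <- annot2[-1, ]
  out3 <- collapse_probes(expr2, annot3)
  expect_equal(attr(out3, "n_unannotated"), 1L)
})

test_that("gene ranking equals the residual-correlation oracle", {
  set.seed(11)
  n <- 50
  age <- runif(n, 25, 74)
  sex <- sample(1:2, n, TRUE)
  aat <- 0.01 * age + rnorm(n)
  G <- matrix(rnorm(8 * n), 8, n, dimnames = list(paste0("g", 1:8), NULL))
  G[1, ] <- aat + 0.02 * age + rnorm(n, sd = 0.2)
  ranked <- rank_genes(G, aat, age, sex)
  # oracle: residualise both sides via lm, then Pearson
  for (g in rownames(G)) {
    r_oracle <- cor(resid(lm(G[g, ] ~ age + sex)), resid(lm(aat ~ age + sex)))
    expect_equal(ranked$r[ranked$gene == g], r_oracle, tolerance = 1e-10)
  }
  expect_equal(ranked$gene[1], "g1")
  # a gene identical to the residualised AAT ranks first with r = 1
  ar <- resid(lm(aat ~ age + sex))
  G2 <- rbind(G, exact = ar)
  ranked2 <- rank_genes(G2, aat, age, sex)
  expect_equal(ranked2$gene[1], "exact")
  expect_equal(ranked2$r[1], 1, tolerance = 1e-12)
  # constant genes get r = 0 by convention
  G3 <- rbind(G, flat = rep(1, n))
  expect_message(ranked3 <- rank_genes(G3, aat, age, sex), "constant")
  expect_equal(ranked3$r[ranked3$gene == "flat"], 0)
})

test_that("the running-sum enrichment score matches the worked example", {
  ranked <- data.frame(gene = paste0("g", 1:5),
                       r = c(0.5, 0.4, 0.3, -0.2, -0.4))
  s <- enrichment_score(ranked, "g1")
  # walk: +0.5, -0.2, -0.2, -0.2, -0.2 cumulated -> max at the hit
  expect_equal(s$es, 0.5)
  expect_equal(s$es_min, 0.5 - 4 * (1 / 5), tolerance = 1e-12)
  # all genes in the set: ES is the max prefix sum of r
  s2 <- enrichment_score(ranked, ranked$gene)
  expect_equal(s2$es, max(cumsum(ranked$r)))
  # zero correlations: the running sum never rises above zero
  ranked0 <- data.frame(gene = paste0("g", 1:5), r = rep(0, 5))
  s3 <- enrichment_score(ranked0, "g1")
  expect_equal(s3$es, 0)
  expect_error(enrichment_score(ranked, "absent"), "empty intersection")
  # independently-coded loop oracle on random instances
  set.seed(21)
  for (i in 1:10) {
    rr <- data.frame(gene = paste0("g", 1:30), r = sort(rnorm(30), TRUE))
    gs <- sample(rr$gene, 7)
    s4 <- enrichment_score(rr, gs)
    o <- es_oracle(rr$gene, rr$r, gs)
    expect_equal(s4$es, o$es, tolerance = 1e-12)
    expect_equal(s4$es_min, o$es_min, tolerance = 1e-12)
  }
})

test_that("ES is invariant to input order under the stable tie-break", {
  set.seed(4)
  n <- 30
  G <- matrix(rnorm(6 * n), 6, n, dimnames = list(paste0("g", 1:6), NULL))
  G[2, ] <- G[1, ]   # duplicated gene rows produce exactly tied correlations
  aat <- rnorm(n)
  age <- runif(n, 25, 74)
  sex <- sample(1:2, n, TRUE)
  r1 <- rank_genes(G, aat, age, sex)
  r2 <- rank_genes(G[sample(6), ], aat, age, sex)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("exhaustive permutation p-values equal the enumeration oracle", {
  set.seed(8)
  n <- 6
  G <- matrix(rnorm(8 * n), 8, n, dimnames = list(paste0("g", 1:8), paste0("s", 1:n)))
  aat <- rnorm(n)
  age <- rep(50, n) + rnorm(n, sd = 0.1)
  sex <- rep(1:2, 3)
  perms <- all_perms(n)
  sets <- list(setA = c("g1", "g3", "g5"), setB = c("g2", "g7"))
  got <- suppressWarnings(normalise_and_test(
    G, aat, age, sex, list(cc = sets), perm_matrix = perms))
  # oracle: residualise, rank and walk for every one of the 720 permutations
  ar <- resid(lm(aat ~ age + sex))
  rg <- function(a) {
    r <- vapply(rownames(G), function(g)
      cor(resid(lm(G[g, ] ~ age + sex)), a), 0)
    ord <- order(-r, names(r))
    list(g = names(r)[ord], r = unname(r[ord]))
  }
  obs <- rg(ar)
  for (sn in names(sets)) {
    o_obs <- es_oracle(obs$g, obs$r, sets[[sn]])
    perm_max <- numeric(ncol(perms))
    perm_min <- numeric(ncol(perms))
    for (k in seq_len(ncol(perms))) {
      pr <- rg(ar[perms[, k]])
      e <- es_oracle(pr$g, pr$r, sets[[sn]])
      perm_max[k] <- e$es
      perm_min[k] <- e$es_min
    }
    if (o_obs$es >= abs(o_obs$es_min)) {
      p_oracle <- (sum(perm_max >= o_obs$es) + 1) / (ncol(perms) + 1)
    } else {
      p_oracle <- (sum(perm_min <= o_obs$es_min) + 1) / (ncol(perms) + 1)
    }
    expect_equal(got$p[got$gene_set == sn], p_oracle, tolerance = 1e-12)
  }
})

test_that("null gene sets have NES near one by construction", {
  # For a fixed side of the running-sum statistic, the observed score of a
  # null set and its permutation scores share a distribution, so the ratio
  # to the permutation mean averages to one.
  cfg <- generator_config(seed = 17, expression = list(
    n_samples = 120L, n_probes = 200L,
    module_sizes = c(m1 = 10L), aat_assoc = c(m1 = 0)))
  ex <- generate_expression(cfg)
  gm <- collapse_probes(ex$expr, ex$annot)
  ranked_for <- function(a) rank_genes(gm, a, ex$age, ex$sex)
  obs_rank <- ranked_for(ex$aat)
  set.seed(3)
  perm_ranks <- lapply(1:100, function(i) ranked_for(sample(ex$aat)))
  set.seed(9)
  ratios <- vapply(1:30, function(i) {
    gs <- sample(rownames(gm), 15)
    obs <- enrichment_score(obs_rank, gs)$es
    perm <- vapply(perm_ranks, function(pr) enrichment_score(pr, gs)$es, 0)
    obs / mean(perm)
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.25)
  # and the full testing surface calls none of the null sets significant
  set.seed(10)
  nulls <- setNames(lapply(1:20, function(i) sample(rownames(gm), 15)),
                    paste0("null", 1:20))
  res <- normalise_and_test(gm, ex$aat, ex$age, ex$sex, list(n = nulls),
                            n_perm = 150, seed = 3)
  expect_equal(sum(res$significant), 0)
})

test_that("summary expression is the sign-aligned first principal component", {
  set.seed(14)
  n <- 100
  base <- rnorm(n)
  expr <- rbind(a = base, b = base, c = rnorm(n))
  se <- summary_expression(expr, c("a", "b"))
  expect_equal(abs(cor(se, base)), 1, tolerance = 1e-10)
  expect_equal(sd(se), 1, tolerance = 1e-12)
  # 2-probe closed form: loadings are (1/sqrt(2), 1/sqrt(2))
  x1 <- rnorm(200)
  x2 <- 0.8 * x1 + rnorm(200, sd = 0.6)
  sub <- t(scale(t(rbind(p1 = x1, p2 = x2))))
  sv <- svd(sub)
  expect_equal(abs(sv$u[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  # coherent module: summary tracks the latent profile
  lat <- rnorm(500)
  mod <- matrix(0.8 * rep(lat, each = 10) + rnorm(5000, sd = 0.6), 10, 500,
                dimnames = list(paste0("m", 1:10), NULL))
  se2 <- summary_expression(mod, rownames(mod))
  expect_gt(abs(cor(se2, lat)), 0.9)
  expect_error(summary_expression(expr, c("a", "zz")), "absent")
  expect_error(summary_expression(expr, "a"), ">= 2")
})

test_that("module regression recovers the generative effect and thresholds", {
  cfg <- generator_config(seed = 23, expression = list(n_samples = 10000L))
  ex <- generate_expression(cfg)
  se <- summary_expression(ex$expr, ex$modules$mod01)
  res <- module_regression(ex$aat, se, ex$age, ex$sex, family_size = 20,
                           standardize = FALSE)
  expect_lt(abs(res$beta - 0.23), 0.05)
  expect_equal(res$bonferroni_threshold, 0.0025)
  res346 <- module_regression(ex$aat, se, ex$age, ex$sex, family_size = 346,
                              standardize = FALSE)
  expect_equal(signif(res346$bonferroni_threshold, 3), 1.45e-4)
  # null module: no association
  se0 <- summary_expression(ex$expr, ex$modules$mod03)
  res0 <- module_regression(ex$aat, se0, ex$age, ex$sex, family_size = 20,
                            standardize = FALSE)
  expect_false(res0$significant)
  # probe order (hence any PC sign ambiguity) does not move the estimate
  se_r <- summary_expression(ex$expr, rev(ex$modules$mod01))
  res_r <- module_regression(ex$aat, se_r, ex$age, ex$sex, family_size = 20,
                             standardize = FALSE)
  expect_equal(res_r$beta, res$beta, tolerance = 1e-10)
})

test_that("core membership p-values equal direct enumeration of the null", {
  set.seed(31)
  n <- 80
  lat <- rnorm(n)
  mod <- matrix(0.9 * rep(lat, each = 8) + rnorm(8 * n, sd = 0.5), 8, n,
                dimnames = list(paste0("m", 1:8), NULL))
  bg <- matrix(rnorm(60 * n), 60, n, dimnames = list(paste0("b", 1:60), NULL))
  expr <- rbind(mod, bg)
  cm <- core_membership(expr, rownames(mod))
  expect_true(all(cm$core))
  expect_equal(min(cm$p), 1 / 61)    # add-one floor with 60 null probes
  # brute-force quantile of the null correlation vector
  se <- summary_expression(expr, rownames(mod))
  null_r <- abs(apply(bg, 1, cor, se))
  for (i in seq_len(nrow(cm))) {
    obs_r <- abs(cor(expr[cm$probe[i], ], se))
    expect_equal(cm$p[i], (sum(null_r >= obs_r) + 1) / 61, tolerance = 1e-12)
  }
  # a probe orthogonal to the summary is excluded
  expr2 <- rbind(expr, ortho = resid(lm(rnorm(n) ~ se)))
  cm2 <- core_membership(expr2, c(rownames(mod), "ortho"))
  expect_false(cm2$core[cm2$probe == "ortho"])
  expect_error(core_membership(expr[1:20, ], rownames(mod)), ">= 50")
})

test_that("held-out noise probes receive uniform membership p-values", {
  # Probes that do not enter the module's principal component are the
  # correctly-calibrated null for the membership test; their p-values are
  # uniform across seeds.
  ps <- vapply(1:40, function(s) {
    set.seed(400 + s)
    n <- 60
    expr <- matrix(rnorm(70 * n), 70, n,
                   dimnames = list(paste0("p", 1:70), NULL))
    se <- summary_expression(expr, paste0("p", 1:10))
    null_r <- abs(apply(expr[21:70, ], 1, cor, se))
    held <- abs(cor(expr[11, ], se))
    (sum(null_r >= held) + 1) / 51
  }, 0)
  expect_lt(abs(mean(ps) - 0.5), 0.15)     # centred as uniform
  expect_lt(mean(ps < 0.1), 0.3)           # no pile-up of small p
})

test_that("pure-noise modules inflate their own membership scores", {
  # The module's probes enter the principal component they are tested
  # against, so even a noise module retains most of its probes; the
  # membership test is calibrated only for held-out probes.
  set.seed(71)
  n <- 60
  expr <- matrix(rnorm(80 * n), 80, n, dimnames = list(paste0("p", 1:80), NULL))
  cm <- core_membership(expr, paste0("p", 1:12))
  expect_gt(mean(cm$core), 0.05)
})
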