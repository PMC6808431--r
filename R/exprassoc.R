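# Transcriptional association stage: probe collapsing, correlation-ranked
# gene set enrichment with the literal running-sum rule and
# sample-permutation normalisation, module eigengene (summary expression)
# association, and the core-membership permutation test.

#' Collapse probes to genes by per-sample maximum
#'
#' For genes carried by multiple probes, the gene's expression in each
#' sample is the maximum across that gene's probes. Probes without gene
#' annotation are dropped (count reported in attribute `n_unannotated`).
#'
#' @param expr probes x samples numeric matrix with probe rownames.
#' @param annot data.frame with columns `probe`, `gene`.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(expr, annot) {
  stopifnot_msg(!is.null(rownames(expr)), "expr must have probe rownames")
  gene <- annot$gene[match(rownames(expr), annot$probe)]
  dropped <- sum(is.na(gene))
  keep <- !is.na(gene)
  expr <- expr[keep, , drop = FALSE]
  gene <- gene[keep]
  genes <- unique(gene)
  out <- matrix(NA_real_, length(genes), ncol(expr),
                dimnames = list(genes, colnames(expr)))
  idx <- split(seq_len(nrow(expr)), gene)
  for (g in names(idx)) {
    rows <- idx[[g]]
    out[g, ] <- if (length(rows) == 1L) expr[rows, ] else
      apply(expr[rows, , drop = FALSE], 2, max)
  }
  attr(out, "n_unannotated") <- dropped
  out
}

# Residualise the rows of a matrix (or a vector) on age + sex.
residualize <- function(x, age, sex) {
  X <- cbind(1, age, sex)
  if (is.matrix(x)) {
    t(x) - X %*% solve(crossprod(X), crossprod(X, t(x)))
  } else {
    x - X %*% solve(crossprod(X), crossprod(X, x))
  }
}

#' Rank genes by AAT-associated differential expression
#'
#' Both the gene expression rows and the log AAT vector are residualised on
#' age and sex, then the Pearson correlation of each gene with AAT is
#' computed and genes are sorted in descending order of correlation
#' (ties broken by stable gene-id order). Constant genes get r = 0 by
#' convention.
#'
#' @param gene_mat genes x samples matrix (after [collapse_probes()]).
#' @param aat log-transformed AAT levels (or any already-log biomarker).
#' @param age,sex per-sample covariates (sex coded 1/2).
#' @return data.frame `gene`, `r`, in descending `r` order.
#' @export
rank_genes <- function(gene_mat, aat, age, sex) {
  n <- ncol(gene_mat)
  stopifnot_msg(length(aat) == n && length(age) == n && length(sex) == n,
                "samples of expression, AAT and covariates must match")
  stopifnot_msg(n >= 10, "at least 10 samples required")
  Gr <- residualize(gene_mat, age, sex)      # samples x genes
  ar <- drop(residualize(aat, age, sex))
  sds <- apply(Gr, 2, stats::sd)
  r <- rep(0, ncol(Gr))
  # constant genes (up to residualisation round-off) get r = 0 by convention
  nz <- sds > 1e-10 * max(sds, 1) & apply(gene_mat, 1, stats::sd) > 0
  r[nz] <- suppressWarnings(stats::cor(Gr[, nz, drop = FALSE], ar))
  if (any(!nz)) message(sprintf("rank_genes: %d constant genes set to r = 0", sum(!nz)))
  df <- data.frame(gene = rownames(gene_mat), r = r, stringsAsFactors = FALSE)
  df[order(-df$r, df$gene), , drop = FALSE]
}

#' Enrichment score by the literal running-sum rule
#'
#' Walking the ranked gene list in descending correlation order, a gene in
#' the set increments the running sum by its correlation with AAT; a gene
#' outside the set decrements it by 1/N where N is the total number of
#' ranked genes. The enrichment score is the maximum of the running sum
#' (the signed minimum is also returned for negative enrichment). A
#' `canonical` switch instead uses the classic weighting (hits normalised
#' by the sum of |r| over the set, misses by 1/(N - set size)).
#'
#' @param ranked data.frame from [rank_genes()] (`gene`, `r`, descending).
#' @param gene_set character vector of gene ids.
#' @param canonical use the classic increment scheme instead.
#' @return list with `es` (max of running sum), `es_min`, and `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, canonical = FALSE) {
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) stop("gene set has empty intersection with the ranked list",
                      call. = FALSE)
  N <- nrow(ranked)
  if (canonical) {
    denom <- sum(abs(ranked$r[hit]))
    inc <- ifelse(hit, abs(ranked$r) / denom, -1 / (N - sum(hit)))
  } else {
    inc <- ifelse(hit, ranked$r, -1 / N)
  }
  rs <- cumsum(inc)
  list(es = max(rs), es_min = min(rs), n_hits = sum(hit))
}

#' Permutation-normalised enrichment over gene set collections
#'
#' Sample labels of the (age/sex-residualised) AAT vector are shuffled
#' `n_perm` times; genes are re-ranked and the enrichment score recomputed
#' for every permutation. The primary statistic is the maximum of the
#' running sum; the minimum covers negative enrichment, with the reported
#' side chosen by magnitude. NES = ES / mean(permutation ES of the same
#' side), so a positive NES marks enrichment among genes upregulated with
#' AAT and a negative NES enrichment among downregulated genes; a null set's
#' NES is ~1 in expectation by construction. The empirical p-value uses the
#' add-one convention against the same-side permutation distribution;
#' Benjamini-Hochberg FDR is applied within each collection separately.
#'
#' @param gene_mat genes x samples matrix.
#' @param aat,age,sex as in [rank_genes()].
#' @param collections named list of collections; each collection is a named
#'   list of gene-id vectors.
#' @param n_perm number of sample permutations (a warning below 100).
#' @param seed permutation seed.
#' @param canonical passed to [enrichment_score()].
#' @param perm_matrix optional explicit samples x permutations index matrix
#'   (e.g. an exhaustive enumeration); overrides `n_perm`/`seed`.
#' @return data.frame: collection, gene_set, size, es, nes, p, fdr,
#'   significant (FDR < 0.05).
#' @export
normalise_and_test <- function(gene_mat, aat, age, sex, collections,
                               n_perm = 1000L, seed = 1L, canonical = FALSE,
                               perm_matrix = NULL) {
  if (!is.null(perm_matrix)) n_perm <- ncol(perm_matrix)
  if (n_perm < 100L) warning("n_perm < 100 gives coarse permutation p-values")
  n <- ncol(gene_mat)
  Gr <- residualize(gene_mat, age, sex)  # samples x genes
  Gs <- scale(Gr)
  ar <- drop(residualize(aat, age, sex))
  genes <- rownames(gene_mat)
  rank_with <- function(a) {
    as_ <- scale(a)[, 1L]
    sds <- attr(Gs, "scaled:scale")
    r <- rep(0, length(genes))
    nz <- sds > 1e-10 * max(sds, 1)
    r[nz] <- drop(crossprod(Gs[, nz, drop = FALSE], as_)) / (n - 1)
    ord <- order(-r, genes)
    list(gene = genes[ord], r = r[ord])
  }
  obs_rank <- rank_with(ar)
  obs_rank_df <- data.frame(gene = obs_rank$gene, r = obs_rank$r,
                            stringsAsFactors = FALSE)
  if (is.null(perm_matrix)) {
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n))
  } else {
    perms <- perm_matrix
  }
  perm_ranks <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    pr <- rank_with(ar[perms[, i]])
    perm_ranks[[i]] <- data.frame(gene = pr$gene, r = pr$r,
                                  stringsAsFactors = FALSE)
  }
  out <- list()
  for (coll in names(collections)) {
    sets <- collections[[coll]]
    res <- lapply(names(sets), function(sn) {
      gs <- intersect(sets[[sn]], genes)
      if (length(gs) == 0) return(NULL)
      obs <- enrichment_score(obs_rank_df, gs, canonical)
      perm <- vapply(perm_ranks, function(pr) {
        s <- enrichment_score(pr, gs, canonical)
        c(s$es, s$es_min)
      }, c(0, 0))
      if (obs$es >= abs(obs$es_min)) {
        es <- obs$es
        nes <- es / mean(perm[1L, ])
        p <- (sum(perm[1L, ] >= es) + 1) / (n_perm + 1)
      } else {
        es <- obs$es_min
        nes <- -abs(es) / abs(mean(perm[2L, ]))
        p <- (sum(perm[2L, ] <= es) + 1) / (n_perm + 1)
      }
      data.frame(collection = coll, gene_set = sn, size = length(gs),
                 es = es, nes = nes, p = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
    if (is.null(res)) next
    res$fdr <- stats::p.adjust(res$p, method = "BH")
    res$significant <- res$fdr < 0.05
    out[[coll]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Module summary expression profile (eigengene)
#'
#' The first principal-component score vector of the module's probe
#' submatrix (probes standardised), sign-aligned to correlate positively
#' with the module's mean standardised expression, then standardised.
#'
#' @param expr probes x samples matrix.
#' @param module character vector of probe ids (>= 2, all present).
#' @return per-sample numeric vector (SD 1).
#' @export
summary_expression <- function(expr, module) {
  missing_probes <- setdiff(module, rownames(expr))
  stopifnot_msg(length(missing_probes) == 0,
                paste("module probes absent from matrix:",
                      paste(utils::head(missing_probes, 3), collapse = ", ")))
  stopifnot_msg(length(module) >= 2, "module must have >= 2 probes")
  sub <- t(scale(t(expr[module, , drop = FALSE])))  # standardise probes
  sv <- svd(sub, nu = 0, nv = 1)
  score <- sv$v[, 1L]
  if (stats::cor(score, colMeans(sub)) < 0) score <- -score
  scale(score)[, 1L]
}

#' Regression of AAT on a module's summary expression
#'
#' Standardised log AAT is regressed on the summary expression profile
#' adjusting for age and sex; the coefficient is the change in SDs of AAT
#' per SD of coordinated module expression.
#'
#' @param aat positive AAT concentrations (log-standardised internally) or
#'   an already-standardised vector if `standardize = FALSE`.
#' @param summary_expr output of [summary_expression()].
#' @param age,sex covariates (sex coded 1/2).
#' @param family_size number of modules tested (Bonferroni threshold
#'   0.05/family_size).
#' @param standardize log-transform and standardise `aat` first.
#' @return one-row data.frame: beta, se, ci_lo, ci_hi, p, bonferroni_threshold,
#'   significant.
#' @export
module_regression <- function(aat, summary_expr, age, sex, family_size = 20L,
                              standardize = TRUE) {
  y <- if (standardize) scale(log(aat))[, 1L] else aat
  fit <- stats::lm(y ~ summary_expr + age + factor(sex, levels = 1:2))
  qrf <- qr(stats::model.matrix(fit))
  stopifnot_msg(qrf$rank == ncol(stats::model.matrix(fit)),
                "rank-deficient design")
  s <- summary(fit)$coefficients
  beta <- s["summary_expr", "Estimate"]
  se <- s["summary_expr", "Std. Error"]
  p <- s["summary_expr", "Pr(>|t|)"]
  thr <- 0.05 / family_size
  data.frame(beta = beta, se = se, ci_lo = beta - 1.96 * se,
             ci_hi = beta + 1.96 * se, p = p, bonferroni_threshold = thr,
             significant = p < thr)
}

#' Core module membership by permutation against out-of-module probes
#'
#' Each module probe's |correlation| with the module's summary expression is
#' compared against the null distribution of |correlation| between the
#' summary profile and all probes outside the module; empirical p-values use
#' the add-one convention, are BH-adjusted within the module, and probes
#' with FDR < `fdr` are the core set.
#'
#' @param expr probes x samples matrix.
#' @param module character vector of module probe ids.
#' @param fdr FDR threshold for core membership.
#' @param min_null minimum number of out-of-module probes required.
#' @return data.frame: probe, r, p, fdr_adjusted, core.
#' @export
core_membership <- function(expr, module, fdr = 0.05, min_null = 50L) {
  null_probes <- setdiff(rownames(expr), module)
  stopifnot_msg(length(null_probes) >= min_null,
                sprintf("need >= %d out-of-module probes for the null", min_null))
  se <- summary_expression(expr, module)
  cors <- function(probes) {
    abs(drop(stats::cor(t(expr[probes, , drop = FALSE]), se)))
  }
  obs <- cors(module)
  null <- cors(null_probes)
  m <- length(null)
  p <- vapply(obs, function(o) (sum(null >= o) + 1) / (m + 1), 0)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(probe = module, r = obs, p = p, fdr_adjusted = padj,
             core = padj < fdr, stringsAsFactors = FALSE)
}

#' Read gene set collections from GMT files
#'
#' @param paths named character vector of GMT file paths (names become
#'   collection names).
#' @return named list of collections (each a named list of gene vectors).
#' @export
read_gmt_collections <- function(paths) {
  out <- lapply(paths, function(p) {
    lines <- readLines(p)
    sets <- lapply(lines, function(l) {
      f <- strsplit(l, "\t")[[1L]]
      f[-(1:2)]
    })
    names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1L]][1L], "")
    sets
  })
  names(out) <- names(paths)
  out
}
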