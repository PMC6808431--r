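# Preprocessing of NMR feature matrices and imputation targets:
# detection-limit zero replacement, completeness filtering, log transform and
# standardisation with stored (replayable) parameters.

#' Replace detection-limit zeros by the cohort minimum positive value
#'
#' NMR concentrations below the platform's lower detection limit arrive as
#' exact zeros. To permit a log transform, every zero is replaced by the
#' minimum positive value observed for the same feature in the same cohort,
#' approximating that feature's detection limit. The replacement values are
#' returned so the transform can be replayed on new data from the same
#' cohort.
#'
#' @param mat numeric matrix, samples x features, non-negative concentrations
#'   (missing values allowed and left untouched).
#' @return list with `matrix` (zeros replaced) and `params`, a named numeric
#'   vector of replacement values for the features that contained zeros
#'   (empty if none).
#' @export
replace_zeros <- function(mat) {
  stopifnot_msg(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  stopifnot_msg(all(mat >= 0, na.rm = TRUE), "negative concentrations are not allowed")
  repl <- numeric(0)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    zero <- !is.na(x) & x == 0
    if (!any(zero)) next
    pos <- x[!is.na(x) & x > 0]
    if (length(pos) == 0L) {
      stop(sprintf("feature '%s' is entirely zero; no minimum positive value exists",
                   colnames(mat)[j]), call. = FALSE)
    }
    m <- min(pos)
    mat[zero, j] <- m
    repl[colnames(mat)[j]] <- m
  }
  list(matrix = mat, params = repl)
}

#' Drop samples with any missing feature value
#'
#' @param mat numeric matrix, samples x features.
#' @param targets optional numeric matrix/vector of target measurements on the
#'   same samples; subset alongside the features.
#' @return list with `matrix`, `targets` (or NULL), `n_dropped`.
#' @export
drop_incomplete <- function(mat, targets = NULL) {
  keep <- stats::complete.cases(mat)
  if (!any(keep)) stop("all samples have missing feature data", call. = FALSE)
  out <- list(matrix = mat[keep, , drop = FALSE], n_dropped = sum(!keep))
  if (!is.null(targets)) {
    out$targets <- if (is.matrix(targets) || is.data.frame(targets)) {
      targets[keep, , drop = FALSE]
    } else targets[keep]
  }
  out
}

#' Log transform and standardise a feature matrix
#'
#' Applies `log` then centring/scaling per column. In fit mode (no `params`)
#' the column log-means and log-SDs are estimated (sample SD, n-1 convention)
#' and returned; in apply mode the stored parameters are reused so a new
#' cohort is expressed on the training cohort's scale (no re-centring).
#' Columns listed in `no_log` (e.g. already-standardised age) are centred and
#' scaled without the log; columns in `passthrough` (e.g. sex coded 1 = men,
#' 2 = women) are left untouched.
#'
#' @param mat numeric matrix, samples x columns.
#' @param params optional parameter list from a previous fit-mode call.
#' @param no_log character vector of column names standardised without log.
#' @param passthrough character vector of column names copied unchanged.
#' @return list with `matrix` (transformed) and `params` (list with `mean`,
#'   `sd`, `no_log`, `passthrough`).
#' @export
log_standardize <- function(mat, params = NULL, no_log = character(0),
                            passthrough = character(0)) {
  stopifnot_msg(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  cn <- colnames(mat)
  stopifnot_msg(!is.null(cn) && !anyDuplicated(cn), "columns must be uniquely named")
  if (!is.null(params)) {
    no_log <- params$no_log
    passthrough <- params$passthrough
  }
  log_cols <- setdiff(cn, c(no_log, passthrough))
  bad <- which(mat[, log_cols, drop = FALSE] <= 0, arr.ind = TRUE)
  if (length(bad) > 0) {
    stop(sprintf("non-positive value in log column '%s', row %d (run replace_zeros first)",
                 log_cols[bad[1, 2]], bad[1, 1]), call. = FALSE)
  }
  out <- mat
  out[, log_cols] <- log(mat[, log_cols, drop = FALSE])
  scale_cols <- c(log_cols, intersect(no_log, cn))
  if (is.null(params)) {
    mu <- colMeans(out[, scale_cols, drop = FALSE])
    sdv <- apply(out[, scale_cols, drop = FALSE], 2, stats::sd)
    stopifnot_msg(all(sdv > 0), "constant column cannot be standardised")
    params <- list(mean = mu, sd = sdv, no_log = no_log, passthrough = passthrough)
  }
  for (j in scale_cols) {
    out[, j] <- (out[, j] - params$mean[[j]]) / params$sd[[j]]
  }
  list(matrix = out, params = params)
}

#' Drop derived-ratio NMR features by name
#'
#' Derived ratios inherit missingness from low-concentration numerators or
#' denominators and are excluded from model training. A feature is treated as
#' a ratio when its name matches the given pattern (default: contains
#' "_pct", "_ratio", or ends in "_FA_pct"-style percentage suffixes).
#'
#' @param mat samples x features matrix.
#' @param pattern regular expression identifying ratio features.
#' @return matrix without the matching columns.
#' @export
drop_ratio_features <- function(mat, pattern = "(_pct$|_ratio$|_FA$|^Ratio_)") {
  drop <- grepl(pattern, colnames(mat))
  mat[, !drop, drop = FALSE]
}
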