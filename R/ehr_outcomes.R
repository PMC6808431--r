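# Aggregation of ICD-10 coded registry records into per-person
# incident/prevalent outcome status, with three-digit code and code-range
# matching, boundary conventions, and the eligibility rules for the scan.

ICD10_PATTERN <- "^[A-Z][0-9]{2}[0-9A-Z]*$"

#' Expand an outcome code specification to its three-digit codes
#'
#' A specification is a single three-digit code ("I50"), an inclusive range
#' within one letter block ("I70-I79", "J09-J18"), or a comma-separated
#' combination of those.
#'
#' @param spec character specification.
#' @return character vector of three-digit codes covered.
#' @export
expand_code_spec <- function(spec) {
  parts <- trimws(strsplit(spec, ",")[[1L]])
  out <- character(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE)) {
      ends <- trimws(strsplit(p, "-", fixed = TRUE)[[1L]])
      stopifnot_msg(length(ends) == 2L &&
                      all(grepl("^[A-Z][0-9]{2}$", ends)) &&
                      substr(ends[1], 1, 1) == substr(ends[2], 1, 1),
                    sprintf("malformed code range '%s'", p))
      lo <- as.integer(substr(ends[1], 2, 3))
      hi <- as.integer(substr(ends[2], 2, 3))
      stopifnot_msg(lo <= hi, sprintf("range start exceeds end in '%s'", p))
      out <- c(out, sprintf("%s%02d", substr(ends[1], 1, 1), lo:hi))
    } else {
      stopifnot_msg(grepl("^[A-Z][0-9]{2}$", p),
                    sprintf("malformed three-digit code '%s'", p))
      out <- c(out, p)
    }
  }
  unique(out)
}

#' Match an ICD-10 record code against an outcome definition
#'
#' Matching is at three-digit accuracy: the record's three-character prefix
#' must be among the codes covered by the definition.
#'
#' @param code ICD-10 record code (>= 3 characters).
#' @param definition code specification as in [expand_code_spec()].
#' @return logical.
#' @export
match_code <- function(code, definition) {
  stopifnot_msg(all(grepl(ICD10_PATTERN, code)),
                sprintf("malformed ICD-10 code '%s'", code[!grepl(ICD10_PATTERN, code)][1]))
  substr(code, 1, 3) %in% expand_code_spec(definition)
}

#' Load registry records from CSV, rejecting ICD-9-style codes
#'
#' The pipeline consumes pre-mapped ICD-10 codes. Purely numeric (ICD-9
#' style) codes are rejected with a pointer to the General Equivalence
#' Mapping conversion that must be applied upstream.
#'
#' @param path CSV with columns id, event_age, icd10, source.
#' @return validated data.frame.
#' @export
load_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_msg(all(c("id", "event_age", "icd10", "source") %in% names(rec)),
                "records must have columns id, event_age, icd10, source")
  icd9 <- grepl("^[0-9]", rec$icd10)
  if (any(icd9)) {
    stop(sprintf(paste("records contain %d ICD-9-style (numeric) codes, e.g. '%s';",
                       "convert to ICD-10 upstream using the CDC General",
                       "Equivalence Mappings before loading"),
                 sum(icd9), rec$icd10[which(icd9)[1]]), call. = FALSE)
  }
  bad <- !grepl(ICD10_PATTERN, rec$icd10)
  stopifnot_msg(!any(bad), sprintf("malformed ICD-10 code '%s'", rec$icd10[which(bad)[1]]))
  stopifnot_msg(all(rec$event_age >= 0), "event ages must be non-negative")
  rec
}

#' Aggregate records into per-person incident/prevalent outcome status
#'
#' Incident status is the earliest matching event in
#' `(baseline, baseline + followup_years]`; prevalent status is any matching
#' event at or before baseline (an event exactly at baseline counts as
#' prevalent, not incident). Main and side diagnoses are treated equally.
#' Persons without an incident event are censored at baseline + follow-up.
#'
#' @param records data.frame with id, event_age, icd10, source.
#' @param definitions named list (or named character vector) of code
#'   specifications per outcome.
#' @param baseline data.frame with `id` and `baseline_age` covering every
#'   person in the analysis set (persons absent from `records` simply have
#'   no events).
#' @param followup_years length of the incident window.
#' @return long data.frame: id, outcome, prevalent, incident, event_age
#'   (NA unless incident), censor_age.
#' @export
aggregate_outcomes <- function(records, definitions, baseline,
                               followup_years = 8) {
  stopifnot_msg(all(c("id", "baseline_age") %in% names(baseline)),
                "baseline must have columns id, baseline_age")
  unknown <- setdiff(unique(records$id), baseline$id)
  stopifnot_msg(length(unknown) == 0,
                sprintf("record for unknown person '%s'", unknown[1]))
  if (is.character(definitions)) definitions <- as.list(definitions)
  base_age <- stats::setNames(baseline$baseline_age, baseline$id)
  rec_base <- base_age[records$id]
  out <- vector("list", length(definitions))
  for (i in seq_along(definitions)) {
    spec <- definitions[[i]]
    hits <- records[match_code(records$icd10, spec), , drop = FALSE]
    hb <- rec_base[match_code(records$icd10, spec)]
    prevalent_ids <- unique(hits$id[hits$event_age <= hb])
    inc_mask <- hits$event_age > hb & hits$event_age <= hb + followup_years
    inc_hits <- hits[inc_mask, , drop = FALSE]
    first_age <- tapply(inc_hits$event_age, inc_hits$id, min)
    tab <- data.frame(
      id = baseline$id,
      outcome = names(definitions)[i],
      prevalent = as.integer(baseline$id %in% prevalent_ids),
      incident = as.integer(baseline$id %in% names(first_age)),
      event_age = as.numeric(first_age[baseline$id]),
      stringsAsFactors = FALSE)
    tab$censor_age <- ifelse(tab$incident == 1L, tab$event_age,
                             baseline$baseline_age + followup_years)
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-outcome incident and prevalent counts
#'
#' @param table output of [aggregate_outcomes()].
#' @return data.frame outcome, incident, prevalent.
#' @export
outcome_counts <- function(table) {
  agg <- stats::aggregate(cbind(incident, prevalent) ~ outcome, data = table,
                          FUN = sum)
  agg[match(unique(table$outcome), agg$outcome), , drop = FALSE]
}

#' Outcome eligibility and prevalent-adjustment decisions
#'
#' An outcome is analysed only when it has at least `min_incident` incident
#' cases in every cohort (within the biomarker's successfully-imputed
#' subset); prevalent-case adjustment is applied per cohort when that
#' cohort has at least `min_prevalent_adjust` prevalent cases.
#'
#' @param tables named list of [aggregate_outcomes()] outputs, one per
#'   cohort (>= 2 cohorts).
#' @param min_incident,min_prevalent_adjust thresholds.
#' @return data.frame: outcome, analysed, then per-cohort incident counts,
#'   prevalent counts and adjust flags.
#' @export
eligibility <- function(tables, min_incident = 20L, min_prevalent_adjust = 10L) {
  stopifnot_msg(length(tables) >= 2L, "eligibility requires >= 2 cohorts")
  counts <- lapply(tables, outcome_counts)
  outcomes <- unique(unlist(lapply(counts, `[[`, "outcome")))
  res <- data.frame(outcome = outcomes, stringsAsFactors = FALSE)
  analysed <- rep(TRUE, length(outcomes))
  for (cn in names(counts)) {
    cc <- counts[[cn]]
    inc <- cc$incident[match(outcomes, cc$outcome)]
    prev <- cc$prevalent[match(outcomes, cc$outcome)]
    inc[is.na(inc)] <- 0L
    prev[is.na(prev)] <- 0L
    analysed <- analysed & inc >= min_incident
    res[[paste0("incident_", cn)]] <- inc
    res[[paste0("prevalent_", cn)]] <- prev
    res[[paste0("adjust_prevalent_", cn)]] <- prev >= min_prevalent_adjust
  }
  res$analysed <- analysed
  res
}
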