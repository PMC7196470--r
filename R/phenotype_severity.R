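#' Severity classification from longitudinal IQ/DQ scores
#'
#' Cognitive outcome at age six defines absolute disease severity. IQ and
#' developmental-quotient assessments taken at different ages are
#' interpolated by ordinary least squares to age 6; a score above 70 is
#' mild, below 50 severe, 50-70 (inclusive) intermediate. Patients under
#' six are unclassified unless their interpolated score is already below
#' 50, and patients without usable assessments are unclassified.
#'
#' The mild group used in the burden comparisons is further restricted to
#' patients whose SCN1A variant is LoF-class or previously described in
#' Dravet syndrome, so that a mild outcome despite a severe variant class
#' flags likely ameliorating modifiers. Mild-restricted and severe patients
#' together form the "extreme" group.
#'
#' @name phenotype_severity
NULL

SEVERITY_LEVELS <- c("MILD", "INTERMEDIATE", "SEVERE", "UNCLASSIFIED")

#' Interpolate an IQ/DQ score to age six
#'
#' Ordinary least-squares line of score on age, evaluated at age 6. A single
#' assessment is returned unchanged; multiple assessments at one identical
#' age fall back to their mean with a warning.
#'
#' @param ages numeric vector of assessment ages (years).
#' @param scores numeric vector of IQ/DQ scores, same length.
#' @return interpolated score at age 6 (unbounded extrapolation).
#' @export
score_at_six <- function(ages, scores) {
  stopifnot(length(ages) == length(scores), length(ages) >= 1L,
            all(is.finite(ages)), all(is.finite(scores)))
  if (length(ages) == 1L) return(scores)
  if (length(unique(ages)) == 1L) {
    warning("all assessments at the same age; using their mean", call. = FALSE)
    return(mean(scores))
  }
  fit <- stats::lm(scores ~ ages)
  unname(stats::predict(fit, newdata = data.frame(ages = 6)))
}

#' Classify a patient's severity band
#'
#' @param score6 interpolated score at age six, or `NA` if unassessable.
#' @param current_age patient's current age in years.
#' @param unassessable logical; TRUE when no reliable classification can be
#'   made regardless of scores.
#' @return one of `"MILD"`, `"INTERMEDIATE"`, `"SEVERE"`, `"UNCLASSIFIED"`.
#'   Boundary scores of exactly 50 and 70 are INTERMEDIATE. Patients under
#'   age six are UNCLASSIFIED unless score6 < 50.
#' @export
classify_severity <- function(score6, current_age, unassessable = FALSE) {
  if (isTRUE(unassessable) || is.na(score6)) return("UNCLASSIFIED")
  if (current_age < 6) {
    return(if (score6 < 50) "SEVERE" else "UNCLASSIFIED")
  }
  if (score6 > 70) "MILD" else if (score6 < 50) "SEVERE" else "INTERMEDIATE"
}

#' Read a phenotype table
#'
#' TSV columns: `patient_id`, `sex` (male|female), `family_id` (may be
#' empty), `current_age`, `scn1a_lof_or_known_severe` (0/1),
#' `relative_severity` (mild|severe|none), `assessments`
#' (semicolon-separated `age:score` pairs; empty = unassessable).
#'
#' @param path path to the TSV file.
#' @return data.frame with a list-column `assessments` of two-column
#'   matrices (age, score).
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_strict(path,
                        required = c("patient_id", "sex", "family_id",
                                     "current_age", "scn1a_lof_or_known_severe",
                                     "relative_severity", "assessments"),
                        numeric_cols = "current_age")
  df$patient_id <- as.character(df$patient_id)
  df$sex <- toupper(df$sex)
  if (!all(df$sex %in% c("MALE", "FEMALE"))) {
    stop("phenotype table: sex must be male or female", call. = FALSE)
  }
  df$family_id <- ifelse(is.na(df$family_id), NA_character_,
                         as.character(df$family_id))
  df$scn1a_lof_or_known_severe <-
    as.logical(as.integer(df$scn1a_lof_or_known_severe))
  df$relative_severity <- toupper(ifelse(is.na(df$relative_severity), "none",
                                         df$relative_severity))
  rel_map <- c(MILD = "REL_MILD", SEVERE = "REL_SEVERE", NONE = "NONE")
  if (!all(df$relative_severity %in% names(rel_map))) {
    stop("phenotype table: relative_severity must be mild, severe or none",
         call. = FALSE)
  }
  df$relative_severity <- unname(rel_map[df$relative_severity])
  df$assessments <- lapply(df$assessments, parse_assessments)
  df
}

parse_assessments <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("age", "score"))))
  }
  pairs <- strsplit(trimws(strsplit(x, ";", fixed = TRUE)[[1]]), ":", fixed = TRUE)
  ok <- vapply(pairs, length, integer(1)) == 2L
  if (!all(ok)) stop("malformed assessments field: '", x, "'", call. = FALSE)
  m <- t(vapply(pairs, function(p) as.numeric(p), numeric(2)))
  colnames(m) <- c("age", "score")
  if (anyNA(m) || any(m[, "age"] <= 0) || any(m[, "score"] < 0)) {
    stop("malformed assessments field: '", x, "'", call. = FALSE)
  }
  m
}

#' Classify a whole cohort
#'
#' Adds `score6` and `severity` columns to a phenotype table.
#'
#' @param phenotypes data.frame from [read_phenotypes()] (or with the same
#'   shape).
#' @return the input with `score6` (NA for unassessable) and `severity`.
#' @export
classify_cohort <- function(phenotypes) {
  n <- nrow(phenotypes)
  score6 <- rep(NA_real_, n)
  severity <- character(n)
  for (i in seq_len(n)) {
    a <- phenotypes$assessments[[i]]
    if (nrow(a) > 0) score6[i] <- score_at_six(a[, "age"], a[, "score"])
    severity[i] <- classify_severity(score6[i], phenotypes$current_age[i],
                                     unassessable = nrow(a) == 0)
  }
  phenotypes$score6 <- score6
  phenotypes$severity <- severity
  phenotypes
}

#' Analysis groups for the burden comparisons
#'
#' * `MILD_RESTRICTED`: mild patients whose SCN1A variant is LoF-class or
#'   known-severe;
#' * `SEVERE`, `INTERMEDIATE`: as classified;
#' * `EXTREME`: union of MILD_RESTRICTED and SEVERE;
#' * `COMPLETE`: every patient in the table.
#'
#' @param phenotypes classified phenotype table (see [classify_cohort()]).
#' @return named list of character vectors of patient ids.
#' @export
analysis_groups <- function(phenotypes) {
  if (!"severity" %in% names(phenotypes)) {
    phenotypes <- classify_cohort(phenotypes)
  }
  id <- phenotypes$patient_id
  sev <- phenotypes$severity
  mild_restricted <- id[sev == "MILD" & phenotypes$scn1a_lof_or_known_severe]
  severe <- id[sev == "SEVERE"]
  list(MILD_RESTRICTED = mild_restricted,
       SEVERE = severe,
       INTERMEDIATE = id[sev == "INTERMEDIATE"],
       EXTREME = c(mild_restricted, severe),
       COMPLETE = id)
}
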