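#' Reference-ratio burden statistic
#'
#' Absolute variant counts are not comparable between a cohort and a
#' reference database sequenced with different platforms, but within each
#' resource the ratio of counts between two gene sets is. The reference
#' ratio (reference target-set count over reference control-set count) times
#' the cohort's observed control-set count therefore gives the expected
#' cohort count in the target set; the deviation of the observed count from
#' that expectation, expressed as a rounded percentage, is the burden
#' statistic. Significance comes from a two-sided Fisher exact test on the
#' 2x2 table of cohort vs reference counts, with a Bonferroni threshold of
#' 0.05 over the number of tests.
#'
#' @name burden_ratio
NULL

#' Expected cohort count in the target set
#'
#' @param ref_target reference-database count in the target gene set.
#' @param ref_control reference-database count in the control gene set
#'   (must be positive).
#' @param obs_control observed cohort count in the control gene set.
#' @return `(ref_target / ref_control) * obs_control`.
#' @export
expected_count <- function(ref_target, ref_control, obs_control) {
  if (ref_control <= 0) {
    stop("undefined reference ratio: ref_control must be > 0", call. = FALSE)
  }
  (ref_target / ref_control) * obs_control
}

#' Over/underrepresentation percentage
#'
#' The observed count as a percentage of the expected count, rounded to the
#' nearest integer (ties away from zero), minus 100. +22 therefore means
#' 122% of the expected number was observed.
#'
#' @param observed observed integer count.
#' @param expected expected count (must be positive).
#' @return signed integer percentage.
#' @export
overrepresentation_pct <- function(observed, expected) {
  if (expected <= 0) stop("expected must be > 0", call. = FALSE)
  round_half_away(100 * observed / expected) - 100
}

#' Two-sided Fisher exact test on a cohort-vs-reference 2x2 table
#'
#' Exact test on the table `[[obs_target, obs_control], [ref_target,
#' ref_control]]`. The two-sided p-value follows the minimum-likelihood
#' convention: the sum of the probabilities of all tables (with the same
#' margins) no more probable than the observed one. Hypergeometric terms are
#' computed in log space via `lchoose`, so margins in the millions are
#' handled exactly; the support sweep is bounded by the smaller (cohort)
#' margin. Ties in probability are detected with a relative tolerance of
#' 1e-7, as in [stats::fisher.test()].
#'
#' @param obs_target,obs_control cohort counts in target and control sets.
#' @param ref_target,ref_control reference counts in target and control sets.
#' @param conv `"min_likelihood"` (default) or `"double"` (twice the smaller
#'   one-sided tail, capped at 1).
#' @return p-value in \[0, 1\].
#' @export
fisher_ratio_test <- function(obs_target, obs_control, ref_target, ref_control,
                              conv = c("min_likelihood", "double")) {
  conv <- match.arg(conv)
  counts <- c(obs_target, obs_control, ref_target, ref_control)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  r1 <- obs_target + obs_control   # cohort margin (small)
  r2 <- ref_target + ref_control
  c1 <- obs_target + ref_target
  c2 <- obs_control + ref_control
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)

  support <- max(0, r1 - c2):min(r1, c1)
  # log P(top-left = x | margins), hypergeometric
  lp <- lchoose(c1, support) + lchoose(c2, r1 - support) - lchoose(n, r1)
  lp_obs <- lp[support == obs_target]
  ltot <- logsumexp(lp)

  if (conv == "min_likelihood") {
    sel <- lp <= lp_obs + log(1 + 1e-7)
    p <- exp(logsumexp(lp[sel]) - ltot)
  } else {
    lo <- exp(logsumexp(lp[support <= obs_target]) - ltot)
    hi <- exp(logsumexp(lp[support >= obs_target]) - ltot)
    p <- min(1, 2 * min(lo, hi))
  }
  min(1, p)
}

#' Bonferroni significance threshold
#'
#' @param n_tests number of tests in the comparison grid.
#' @return `0.05 / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests) {
  stopifnot(n_tests >= 1)
  0.05 / n_tests
}

#' Build a counts summary
#'
#' Container pairing cohort counts per (gene set, category, patient group)
#' with reference counts per (gene set, MAF threshold).
#'
#' @param cohort data.frame with columns `set`, `category`, `group`, `count`.
#' @param reference data.frame with columns `set`, `maf_threshold`, `count`.
#' @return a `counts_summary` object.
#' @export
counts_summary <- function(cohort, reference) {
  stopifnot(all(c("set", "category", "group", "count") %in% names(cohort)),
            all(c("set", "maf_threshold", "count") %in% names(reference)))
  structure(list(cohort = cohort, reference = reference),
            class = "counts_summary")
}

#' @export
print.counts_summary <- function(x, ...) {
  cat("counts_summary:", nrow(x$cohort), "cohort cells,",
      nrow(x$reference), "reference cells\n")
  invisible(x)
}

#' Tabulate a cohort variant table into a counts summary
#'
#' @param variants qualifying variant rows.
#' @param registry a `gene_registry`.
#' @param groups named list of patient-id vectors (e.g. from
#'   [analysis_groups()]).
#' @param reference reference counts data.frame (`set`, `maf_threshold`,
#'   `count`).
#' @param sets gene sets to tabulate.
#' @param categories variant categories to tabulate.
#' @return a `counts_summary`.
#' @export
tabulate_cohort <- function(variants, registry, groups, reference,
                            sets = c("EPILEPSY", paste0("CTRL", 1:4), "ID"),
                            categories = VARIANT_CATEGORIES) {
  all_ids <- unique(unlist(groups))
  cm <- category_matrix(variants)
  rows <- expand.grid(set = sets, category = categories,
                      group = names(groups), stringsAsFactors = FALSE)
  rows$count <- NA_integer_
  for (s in sets) {
    in_set <- variants$gene %in% genes_in_set(registry, s)
    for (g in names(groups)) {
      in_grp <- in_set & variants$patient_id %in% groups[[g]]
      for (cat in categories) {
        k <- sum(in_grp & cm[, cat])
        rows$count[rows$set == s & rows$category == cat & rows$group == g] <- k
      }
    }
  }
  counts_summary(rows, reference)
}

cohort_count <- function(counts, set, category, group) {
  df <- counts$cohort
  if (set == "CTRL1-4") {
    hit <- df$set %in% paste0("CTRL", 1:4) & df$category == category &
      df$group == group
    if (sum(hit) != 4L) return(NA_integer_)
    return(sum(df$count[hit]))
  }
  hit <- df$set == set & df$category == category & df$group == group
  if (sum(hit) != 1L) return(NA_integer_)
  df$count[hit]
}

reference_count <- function(counts, set, category) {
  thr <- CATEGORY_MAF[[category]]
  df <- counts$reference
  if (set == "CTRL1-4") {
    hit <- df$set %in% paste0("CTRL", 1:4) & df$maf_threshold == thr
    if (sum(hit) != 4L) return(NA_real_)
    return(sum(df$count[hit]))
  }
  hit <- df$set == set & df$maf_threshold == thr
  if (sum(hit) != 1L) return(NA_real_)
  df$count[hit]
}

#' Run the full burden comparison grid
#'
#' One cell per (target set, control set, category, group) combination:
#' observed and expected counts, overrepresentation percentage, two-sided
#' Fisher p-value, and a Bonferroni significance flag. Categories A and B
#' are excluded from this grid because the reference summary carries no
#' CADD-filtered counts.
#'
#' @param counts a `counts_summary`.
#' @param target_sets character vector of target gene sets.
#' @param control_sets character vector of control sets; may include
#'   `"CTRL1-4"` for the pooled controls.
#' @param categories subset of `c("C", "D", "E")`.
#' @param groups character vector of patient-group names present in the
#'   cohort counts.
#' @param n_tests number of tests for the Bonferroni threshold; defaults to
#'   the number of grid cells actually computed.
#' @param conv Fisher two-sided convention, see [fisher_ratio_test()].
#' @return data.frame with one row per cell: `target_set`, `control_set`,
#'   `category`, `group`, `observed`, `expected`, `overrep_pct`, `p_value`,
#'   `significant`, `error`.
#' @export
run_burden_grid <- function(counts, target_sets, control_sets,
                            categories = c("C", "D", "E"), groups,
                            n_tests = NULL, conv = "min_likelihood") {
  stopifnot(inherits(counts, "counts_summary"),
            all(categories %in% c("C", "D", "E")))
  grid <- expand.grid(target_set = target_sets, control_set = control_sets,
                      category = categories, group = groups,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  if (n == 0L) stop("empty burden grid specification", call. = FALSE)
  grid$observed <- NA_integer_
  grid$expected <- NA_real_
  grid$overrep_pct <- NA_real_
  grid$p_value <- NA_real_
  grid$error <- NA_character_
  for (i in seq_len(n)) {
    res <- tryCatch({
      obs_t <- cohort_count(counts, grid$target_set[i], grid$category[i],
                            grid$group[i])
      obs_c <- cohort_count(counts, grid$control_set[i], grid$category[i],
                            grid$group[i])
      ref_t <- reference_count(counts, grid$target_set[i], grid$category[i])
      ref_c <- reference_count(counts, grid$control_set[i], grid$category[i])
      if (anyNA(c(obs_t, obs_c, ref_t, ref_c))) {
        stop("missing count for cell", call. = FALSE)
      }
      exp_t <- expected_count(ref_t, ref_c, obs_c)
      list(observed = obs_t,
           expected = exp_t,
           overrep = overrepresentation_pct(obs_t, exp_t),
           p = fisher_ratio_test(obs_t, obs_c, ref_t, ref_c, conv = conv))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      grid$error[i] <- conditionMessage(res)
    } else {
      grid$observed[i] <- res$observed
      grid$expected[i] <- res$expected
      grid$overrep_pct[i] <- res$overrep
      grid$p_value[i] <- res$p
    }
  }
  computed <- sum(is.na(grid$error))
  if (is.null(n_tests)) n_tests <- max(1L, computed)
  grid$significant <- !is.na(grid$p_value) &
    grid$p_value < bonferroni_threshold(n_tests)
  attr(grid, "n_tests") <- n_tests
  attr(grid, "bonferroni_threshold") <- bonferroni_threshold(n_tests)
  grid
}
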