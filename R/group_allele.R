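#' Allele-fraction comparisons between severity groups
#'
#' Within the epilepsy gene panel, variant loads of the mild, severe and
#' intermediate groups are compared on an allele scale. The allele
#' denominator of a group is the number of genes carrying at least one
#' qualifying variant in any of the compared groups, times two alleles,
#' times the number of patients in the group, minus one allele per X-linked
#' gene per male (males carry a single X). The variant-allele percentage is
#' the group's variant count over this denominator; groups are compared with
#' the same two-sided Fisher exact test used for the burden grid.
#'
#' @name group_allele
NULL

#' Gene universe for a category across compared groups
#'
#' Genes (within a set) with at least one variant of the category in at
#' least one of the compared groups. The denominator is category-specific
#' so that each column of a Table-3-style summary is internally consistent.
#'
#' @param variants qualifying variant rows.
#' @param groups named list of patient-id vectors under comparison.
#' @param category variant category.
#' @param registry a `gene_registry`.
#' @param set_name gene set defining the panel (default EPILEPSY).
#' @return character vector of gene symbols.
#' @export
variant_gene_universe <- function(variants, groups, category, registry,
                                  set_name = "EPILEPSY") {
  ids <- unique(unlist(groups))
  keep <- variants$patient_id %in% ids &
    variants$gene %in% genes_in_set(registry, set_name) &
    category_matrix(variants)[, category]
  sort(unique(variants$gene[keep]))
}

#' Sex- and X-linkage-aware allele denominator for one group
#'
#' @param variants qualifying variant rows.
#' @param groups named list of all patient-id vectors under comparison (the
#'   gene universe spans all of them).
#' @param group name of the target group within `groups`.
#' @param registry a `gene_registry`.
#' @param sex named character vector patient_id -> "MALE"/"FEMALE".
#' @param category variant category defining the gene universe.
#' @param set_name gene set (default EPILEPSY).
#' @return list with `group`, `n_patients`, `n_genes_with_variant`,
#'   `n_x_linked_genes_with_variant`, `n_males`, `total_alleles`.
#' @export
total_alleles <- function(variants, groups, group, registry, sex, category,
                          set_name = "EPILEPSY") {
  stopifnot(group %in% names(groups))
  ids <- groups[[group]]
  universe <- variant_gene_universe(variants, groups, category, registry,
                                    set_name)
  xl <- registry_lookup(registry, "x_linked")
  n_x <- sum(xl[universe], na.rm = TRUE)
  n_males <- sum(sex[ids] == "MALE", na.rm = TRUE)
  total <- length(universe) * 2L * length(ids) - n_x * n_males
  list(group = group,
       n_patients = length(ids),
       n_genes_with_variant = length(universe),
       n_x_linked_genes_with_variant = n_x,
       n_males = n_males,
       total_alleles = as.integer(total))
}

#' Variant-allele fraction of one group for one category
#'
#' @inheritParams total_alleles
#' @return list with `group`, `category`, `n_variants`, `total_alleles`,
#'   `pct_variant_alleles` (full precision; display rounds to 2 decimals).
#' @export
group_fraction <- function(variants, groups, group, registry, sex, category,
                           set_name = "EPILEPSY") {
  denom <- total_alleles(variants, groups, group, registry, sex, category,
                         set_name)
  ids <- groups[[group]]
  keep <- variants$patient_id %in% ids &
    variants$gene %in% genes_in_set(registry, set_name) &
    category_matrix(variants)[, category]
  v <- sum(keep)
  list(group = group, category = category, n_variants = v,
       total_alleles = denom$total_alleles,
       pct_variant_alleles = if (denom$total_alleles > 0)
         100 * v / denom$total_alleles else NA_real_)
}

#' Compare two group fractions with a Fisher exact test
#'
#' Two-sided Fisher exact test on `[[v1, N1 - v1], [v2, N2 - v2]]` where
#' `Ni` is the group's allele denominator.
#'
#' @param f1,f2 results of [group_fraction()] (or lists with `n_variants`
#'   and `total_alleles`).
#' @return two-sided p-value.
#' @export
compare_group_fractions <- function(f1, f2) {
  if (f1$n_variants > f1$total_alleles || f2$n_variants > f2$total_alleles) {
    stop("variant count exceeds allele denominator", call. = FALSE)
  }
  fisher_ratio_test(f1$n_variants, f1$total_alleles - f1$n_variants,
                    f2$n_variants, f2$total_alleles - f2$n_variants)
}

#' Allele-fraction summary across groups and categories
#'
#' Table-3-style summary: one row per (group, category) with the
#' variant-allele percentage, plus pairwise Fisher p-values.
#'
#' @param variants qualifying variant rows.
#' @param groups named list of patient-id vectors (typically mild-restricted,
#'   severe, extreme, intermediate).
#' @param registry a `gene_registry`.
#' @param sex named character vector patient_id -> sex.
#' @param categories categories to report.
#' @param comparisons list of 2-element character vectors naming group pairs
#'   to test; NULL tests all pairs.
#' @param set_name gene set (default EPILEPSY).
#' @return list with data.frames `fractions` and `tests`.
#' @export
group_fraction_table <- function(variants, groups, registry, sex,
                                 categories = VARIANT_CATEGORIES,
                                 comparisons = NULL, set_name = "EPILEPSY") {
  fr <- do.call(rbind, lapply(categories, function(cat) {
    do.call(rbind, lapply(names(groups), function(g) {
      f <- group_fraction(variants, groups, g, registry, sex, cat, set_name)
      data.frame(group = g, category = cat, n_variants = f$n_variants,
                 total_alleles = f$total_alleles,
                 pct_variant_alleles = f$pct_variant_alleles,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(groups), 2, simplify = FALSE)
  }
  tests <- do.call(rbind, lapply(categories, function(cat) {
    do.call(rbind, lapply(comparisons, function(pair) {
      f1 <- group_fraction(variants, groups, pair[1], registry, sex, cat, set_name)
      f2 <- group_fraction(variants, groups, pair[2], registry, sex, cat, set_name)
      data.frame(group1 = pair[1], group2 = pair[2], category = cat,
                 p_value = compare_group_fractions(f1, f2),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(fractions = fr, tests = tests)
}

# Normal-approximation power of a two-sided two-proportion test at level
# alpha, pooled-variance null standard error.
two_prop_power <- function(p1, p2, n1, n2, alpha) {
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((abs(p2 - p1) - z * se0) / se1)
}

#' Minimal detectable variant-allele fraction
#'
#' Smallest fraction `p2 > baseline` at which a two-sided two-proportion
#' test at level `alpha` attains the requested power, given the two allele
#' denominators. Uses the pooled-variance normal approximation and bisection
#' (tolerance 1e-6 on p2). Returns a list with `fraction` (NA when the
#' power is unreachable within (baseline, 1)), `ratio` (fraction /
#' baseline), and `achieved_power`.
#'
#' @param baseline_fraction the reference group's variant-allele fraction
#'   (on the 0-1 scale).
#' @param n1_alleles allele denominator of the group carrying the elevated
#'   fraction.
#' @param n2_alleles allele denominator of the baseline group.
#' @param alpha significance level.
#' @param power target power.
#' @return list with `fraction`, `ratio`, `achieved_power`.
#' @export
required_fraction_for_power <- function(baseline_fraction, n1_alleles,
                                        n2_alleles, alpha = 0.05,
                                        power = 0.8) {
  stopifnot(baseline_fraction > 0, baseline_fraction < 1,
            alpha > 0, alpha < 1, power > 0, power < 1,
            n1_alleles > 0, n2_alleles > 0)
  pw <- function(p2) two_prop_power(baseline_fraction, p2,
                                    n2_alleles, n1_alleles, alpha)
  hi <- 1 - 1e-9
  if (pw(hi) < power) {
    return(list(fraction = NA_real_, ratio = NA_real_,
                achieved_power = pw(hi)))
  }
  lo <- baseline_fraction
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  list(fraction = hi, ratio = hi / baseline_fraction, achieved_power = pw(hi))
}

#' Per-gene mild-vs-severe enrichment ranking
#'
#' For each gene of the panel with at least one variant of the category in
#' either group, a two-sided Fisher exact test on per-gene variant counts
#' against per-gene allele totals (2 per patient, minus one per male for
#' X-linked genes). Genes are split by direction of excess and ranked by
#' ascending p-value within each direction.
#'
#' @param variants qualifying variant rows.
#' @param groups named list with elements `MILD_RESTRICTED` and `SEVERE`
#'   (patient-id vectors).
#' @param category variant category.
#' @param registry a `gene_registry`.
#' @param sex named character vector patient_id -> sex.
#' @param set_name gene set (default EPILEPSY).
#' @return data.frame with `gene`, `direction` (`excess_in_mild` /
#'   `excess_in_severe` / `balanced`), `v_mild`, `v_severe`, `n_mild`,
#'   `n_severe`, `p_value`, ordered by direction then p.
#' @export
rank_genes_by_group <- function(variants, groups, category, registry, sex,
                                set_name = "EPILEPSY") {
  stopifnot(all(c("MILD_RESTRICTED", "SEVERE") %in% names(groups)))
  mild <- groups$MILD_RESTRICTED
  severe <- groups$SEVERE
  panel <- genes_in_set(registry, set_name)
  cm <- category_matrix(variants)[, category]
  keep <- cm & variants$patient_id %in% c(mild, severe)
  skipped <- setdiff(unique(variants$gene[keep]), panel)
  if (length(skipped)) {
    warning("gene(s) absent from the ", set_name, " panel skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "), call. = FALSE)
  }
  keep <- keep & variants$gene %in% panel
  genes <- sort(unique(variants$gene[keep]))
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), direction = character(),
                      v_mild = integer(), v_severe = integer(),
                      n_mild = integer(), n_severe = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  xl <- registry_lookup(registry, "x_linked")
  males_mild <- sum(sex[mild] == "MALE", na.rm = TRUE)
  males_severe <- sum(sex[severe] == "MALE", na.rm = TRUE)
  rows <- lapply(genes, function(g) {
    gm <- keep & variants$gene == g
    v_m <- sum(gm & variants$patient_id %in% mild)
    v_s <- sum(gm & variants$patient_id %in% severe)
    n_m <- 2L * length(mild) - if (isTRUE(xl[[g]])) males_mild else 0L
    n_s <- 2L * length(severe) - if (isTRUE(xl[[g]])) males_severe else 0L
    p <- fisher_ratio_test(v_m, n_m - v_m, v_s, n_s - v_s)
    dir <- if (v_m / n_m > v_s / n_s) "excess_in_mild"
           else if (v_s / n_s > v_m / n_m) "excess_in_severe"
           else "balanced"
    data.frame(gene = g, direction = dir, v_mild = v_m, v_severe = v_s,
               n_mild = n_m, n_severe = n_s, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$direction,
                         c("excess_in_mild", "excess_in_severe", "balanced")),
                   out$p_value, out$gene), ]
  rownames(out) <- NULL
  out
}
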