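# Small registry keeps the generator fast in unit tests; the acceptance
# suite exercises the full-size default.
test_registry <- synthetic_registry(sizes = c(EPILEPSY = 60, CTRL1 = 40,
                                              CTRL2 = 20, CTRL3 = 30,
                                              CTRL4 = 30, ID = 50))

test_that("the same seed reproduces the cohort exactly", {
  cfg <- simulation_config(seed = 101, registry = test_registry)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$phenotypes, s2$phenotypes)
  s3 <- generate_cohort(simulation_config(seed = 102, registry = test_registry))
  expect_false(identical(s1$variants, s3$variants))
})

test_that("generated category counts are nested and match the recorded truth", {
  sim <- generate_cohort(simulation_config(seed = 7, registry = test_registry))
  qual <- sim$variants[qualifies(sim$variants), ]
  cm <- category_matrix(qual)
  expect_true(all(cm[, "A"] <= cm[, "B"]))
  expect_true(all(cm[, "B"] <= cm[, "C"]))
  expect_true(all(cm[, "C"] <= cm[, "D"]))
  expect_true(all(cm[, "D"] <= cm[, "E"]))

  # planted counts (derived from simulation strata) match count_variants
  ph <- classify_cohort(sim$phenotypes)
  grp <- analysis_groups(ph)
  truth <- sim$truth$category_counts
  for (i in sample(nrow(truth), 25)) {
    row <- truth[i, ]
    if (!row$group %in% names(grp)) next
    got <- count_variants(qual, test_registry, row$category, row$set,
                          grp[[row$group]],
                          all_patients = ph$patient_id)
    expect_equal(got, row$count,
                 info = paste(row$set, row$category, row$group))
  }
})

test_that("the severity classifier recovers every assigned band exactly", {
  sim <- generate_cohort(simulation_config(seed = 19, registry = test_registry))
  ph <- classify_cohort(sim$phenotypes)
  expect_identical(ph$severity, sim$truth$patients$severity)
  # interpolated scores equal the planted scores (noiseless linear tracks)
  assessed <- !is.na(sim$truth$patients$score6) &
    vapply(ph$assessments, nrow, integer(1)) > 0
  expect_equal(ph$score6[assessed], sim$truth$patients$score6[assessed],
               tolerance = 1e-8)
  # the default design reproduces the study's group sizes
  grp <- analysis_groups(ph)
  expect_length(grp$MILD_RESTRICTED, 10)
  expect_length(grp$SEVERE, 22)
  expect_length(grp$INTERMEDIATE, 18)
  expect_length(grp$EXTREME, 32)
})

test_that("known SCN1A rows are planted and excluded by the filter", {
  sim <- generate_cohort(simulation_config(seed = 23, registry = test_registry))
  known <- sim$variants[sim$variants$is_known_scn1a, ]
  expect_equal(nrow(known), 87)
  expect_true(all(known$gene == "SCN1A"))
  expect_false(any(sim$variants$is_known_scn1a & qualifies(sim$variants)))
})

test_that("X-linked genes emit at roughly half rate in males", {
  reg <- synthetic_registry(sizes = c(EPILEPSY = 200))
  cfg <- simulation_config(seed = 31, n_patients = 500,
                           group_sizes = c(MILD = 125, SEVERE = 125,
                                           INTERMEDIATE = 125,
                                           UNCLASSIFIED = 125),
                           n_mild_lof = 50, registry = reg,
                           per_gene_rate = 0.2, n_families = 0)
  sim <- generate_cohort(cfg)
  v <- sim$variants[!sim$variants$is_known_scn1a, ]
  sex <- stats::setNames(sim$truth$patients$sex, sim$truth$patients$patient_id)
  xl <- reg$genes$x_linked[match(v$gene, reg$genes$symbol)]
  male <- sex[v$patient_id] == "MALE"
  n_x_genes <- sum(reg$genes$x_linked)
  n_auto <- sum(!reg$genes$x_linked)
  n_m <- sum(sim$truth$patients$sex == "MALE")
  n_f <- 500 - n_m
  rate_male_x <- sum(xl & male) / (n_x_genes * n_m)
  rate_female_x <- sum(xl & !male) / (n_x_genes * n_f)
  expect_equal(rate_male_x / rate_female_x, 0.5, tolerance = 0.2)
  # empirical totals converge to the Poisson expectation
  expected_total <- 0.2 * (n_auto * 500 + n_x_genes * (n_f + 0.5 * n_m))
  expect_equal(nrow(v), expected_total, tolerance = 0.05)
})

test_that("planted enrichment raises rates only in the targeted set and group", {
  cfg <- simulation_config(seed = 47, n_patients = 300,
                           group_sizes = c(MILD = 100, SEVERE = 100,
                                           INTERMEDIATE = 100,
                                           UNCLASSIFIED = 0),
                           n_mild_lof = 100, registry = test_registry,
                           per_gene_rate = 0.3, n_families = 0,
                           enrichment = list(EPILEPSY = c(EXTREME = 2)))
  sim <- generate_cohort(cfg)
  v <- sim$variants[!sim$variants$is_known_scn1a, ]
  sev <- stats::setNames(sim$truth$patients$severity,
                         sim$truth$patients$patient_id)
  epi <- genes_in_set(test_registry, "EPILEPSY")
  rate <- function(set_genes, groups) {
    sum(v$gene %in% set_genes & sev[v$patient_id] %in% groups) /
      sum(sev %in% groups)
  }
  extr <- c("MILD", "SEVERE")
  expect_equal(rate(epi, extr) / rate(epi, "INTERMEDIATE"), 2,
               tolerance = 0.15)
  ctl <- genes_in_set(test_registry, "CTRL1-4")
  expect_equal(rate(ctl, extr) / rate(ctl, "INTERMEDIATE"), 1,
               tolerance = 0.15)
})

test_that("reference counts are monotone in the MAF threshold", {
  sim <- generate_cohort(simulation_config(seed = 53, registry = test_registry))
  for (s in unique(sim$reference$set)) {
    cnt <- sim$reference$count[sim$reference$set == s][
      order(sim$reference$maf_threshold[sim$reference$set == s])]
    expect_true(all(diff(cnt) >= 0))
  }
})
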