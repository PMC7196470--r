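test_that("allele denominators follow the 2N-minus-male-X formula", {
  reg <- small_registry()
  sex <- c(P1 = "FEMALE", P2 = "MALE", P3 = "MALE", P4 = "FEMALE")
  # 1 female patient, 3 variant-bearing autosomal genes -> 3 x 2 x 1 = 6
  v <- make_variant(gene = c("GENEA", "GENEB", "GENEC"), patient = "P1",
                    af_exome = 0.001, cadd = 25)
  d <- total_alleles(v, list(G = "P1"), "G", reg, sex, "C")
  expect_equal(d$total_alleles, 6)

  # 3 patients (2 male), 4 variant-bearing genes of which 1 X-linked:
  # 4 x 2 x 3 - 1 x 2 = 22
  v2 <- make_variant(gene = c("GENEA", "GENEB", "GENEC", "GENEX"),
                     patient = c("P1", "P2", "P2", "P3"),
                     af_exome = 0.001, cadd = 25)
  d2 <- total_alleles(v2, list(G = c("P1", "P2", "P3")), "G", reg, sex, "C")
  expect_equal(d2$n_genes_with_variant, 4)
  expect_equal(d2$n_x_linked_genes_with_variant, 1)
  expect_equal(d2$n_males, 2)
  expect_equal(d2$total_alleles, 22)

  # all-female group: X-linkage does not change the denominator (the gene
  # universe still spans both compared groups)
  d3 <- total_alleles(v2, list(G1 = c("P1", "P4"), G2 = c("P2", "P3")),
                      "G1", reg, c(P1 = "FEMALE", P4 = "FEMALE",
                                   P2 = "MALE", P3 = "MALE"), "C")
  expect_equal(d3$total_alleles, 4 * 2 * 2)
})

test_that("the gene universe spans all compared groups, not just the target", {
  reg <- small_registry()
  sex <- c(P1 = "FEMALE", P2 = "FEMALE")
  # P2 carries the only GENEB variant, but P1's denominator must include it
  v <- make_variant(gene = c("GENEA", "GENEB"), patient = c("P1", "P2"),
                    af_exome = 0.001, cadd = 25)
  d <- total_alleles(v, list(G1 = "P1", G2 = "P2"), "G1", reg, sex, "C")
  expect_equal(d$n_genes_with_variant, 2)
  expect_equal(d$total_alleles, 4)
})

test_that("group fractions are linear in the variant count", {
  reg <- small_registry()
  sex <- c(P1 = "FEMALE", P2 = "FEMALE")
  v1 <- make_variant(gene = "GENEA", patient = "P1", af_exome = 0.001, cadd = 25)
  v2 <- rbind(v1, make_variant(gene = "GENEA", patient = "P1",
                               af_exome = 0.002, cadd = 30, hgvs = "c.99A>G"))
  groups <- list(G = "P1")
  f1 <- group_fraction(v1, groups, "G", reg, sex, "C")
  f2 <- group_fraction(v2, groups, "G", reg, sex, "C")
  expect_equal(f1$pct_variant_alleles, 100 * 1 / 2)
  expect_equal(f2$pct_variant_alleles, 2 * f1$pct_variant_alleles)
  # zero variants of a category -> zero percent on that category's universe
  f0 <- group_fraction(v1, groups, "G", reg, sex, "A")
  expect_equal(f0$n_variants, 1)  # cadd 25 > 20, af < 0.01: type A too
})

test_that("group comparison shares its statistical core with the ratio test", {
  f1 <- list(n_variants = 12, total_alleles = 400)
  f2 <- list(n_variants = 30, total_alleles = 500)
  expect_equal(compare_group_fractions(f1, f2),
               fisher_ratio_test(12, 388, 30, 470), tolerance = 1e-15)
  expect_equal(compare_group_fractions(f1, f1), 1)
  expect_error(compare_group_fractions(list(n_variants = 5, total_alleles = 3),
                                       f2), "exceeds")
})

test_that("group outputs are invariant to patient label permutations", {
  reg <- small_registry()
  set.seed(11)
  pats <- paste0("P", 1:8)
  sex <- stats::setNames(rep(c("MALE", "FEMALE"), 4), pats)
  v <- make_variant(gene = sample(c("GENEA", "GENEB", "GENEX"), 40, TRUE),
                    patient = sample(pats, 40, TRUE),
                    af_exome = runif(40, 0, 0.04), cadd = runif(40, 5, 35))
  g <- list(A = pats[1:4], B = pats[5:8])
  f_ab <- group_fraction(v, g, "A", reg, sex, "D")
  # permute rows of the variant table; results identical
  v_perm <- v[sample(nrow(v)), ]
  f_ab2 <- group_fraction(v_perm, g, "A", reg, sex, "D")
  expect_equal(f_ab, f_ab2)
})

test_that("power inversion is monotone and flags unreachable targets", {
  r1 <- required_fraction_for_power(0.04, 2000, 2000, alpha = 0.05, power = 0.8)
  r2 <- required_fraction_for_power(0.04, 8000, 8000, alpha = 0.05, power = 0.8)
  expect_true(r1$fraction > 0.04)
  expect_lt(r2$fraction, r1$fraction)  # more alleles, smaller detectable effect
  expect_equal(r1$achieved_power, 0.8, tolerance = 1e-3)
  # a tiny sample cannot reach 99.999% power at any fraction below 1
  tiny <- required_fraction_for_power(0.5, 3, 3, alpha = 1e-6, power = 0.99999)
  expect_true(is.na(tiny$fraction))
})

test_that("the detectable-effect ratio on the patient scale is several-fold", {
  # at a 4.03% baseline with 50 patients per group, the minimal detectable
  # fraction is near 25% (roughly six-fold); a qualitative anchor only,
  # since the published figure names no method
  res <- required_fraction_for_power(0.0403, 50, 50, alpha = 0.05, power = 0.8)
  expect_equal(res$fraction, 0.25, tolerance = 0.25)
  expect_gt(res$ratio, 4)
  expect_lt(res$ratio, 8)
  # far above the observed 1.1-fold difference between the groups
  expect_gt(res$ratio, 1.1)
})

test_that("per-gene ranking finds planted direction and orders by p", {
  reg <- small_registry()
  mild <- paste0("M", 1:5); severe <- paste0("S", 1:5)
  sex <- stats::setNames(rep("FEMALE", 10), c(mild, severe))
  v <- rbind(
    make_variant(gene = "GENEA", patient = severe, af_exome = 0.001, cadd = 25),
    make_variant(gene = "GENEB", patient = mild[1], af_exome = 0.001, cadd = 25))
  groups <- list(MILD_RESTRICTED = mild, SEVERE = severe)
  rk <- rank_genes_by_group(v, groups, "C", reg, sex)
  expect_identical(rk$direction[rk$gene == "GENEA"], "excess_in_severe")
  expect_identical(rk$direction[rk$gene == "GENEB"], "excess_in_mild")
  expect_true(rk$p_value[rk$gene == "GENEA"] < rk$p_value[rk$gene == "GENEB"])
  # genes outside the panel are skipped with a warning
  v_out <- rbind(v, make_variant(gene = "NOTINPANEL", patient = mild[1],
                                 af_exome = 0.001, cadd = 25))
  expect_warning(rank_genes_by_group(v_out, groups, "C", reg, sex),
                 "skipped")
})
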