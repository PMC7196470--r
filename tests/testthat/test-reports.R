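family_fixture <- function() {
  # F1: severe proband PS, mild father PM; shared and private type-A variants
  ph <- make_phenotypes(c("PS", "PM", "PX"), family_id = c("F1", "F1", NA),
                        relative = c("REL_SEVERE", "REL_MILD", "NONE"))
  v <- rbind(
    make_variant(gene = "GENEA", patient = "PS", af_exome = 0, cadd = 26.1,
                 hgvs = "c.452T>C"),                      # severe-only
    make_variant(gene = "GENEB", patient = c("PS", "PM"), af_exome = 0.002,
                 cadd = 24, hgvs = "c.100G>A"),           # shared -> excluded
    make_variant(gene = "GENEC", patient = "PM", af_exome = 0.001, cadd = 30,
                 hgvs = "c.7C>T"),                        # mild-only
    make_variant(gene = "GENEC", patient = "PS", af_exome = 0.02, cadd = 33,
                 hgvs = "c.8C>T"))                        # type D, not A
  list(ph = ph, v = v)
}

test_that("family reports list only variants private to one severity label", {
  fx <- family_fixture()
  rep <- family_private_variants(fx$v, fx$ph, "F1")
  expect_identical(rep$severe_only$gene, "GENEA")
  expect_identical(rep$severe_only$hgvs, "c.452T>C")
  expect_identical(rep$severe_only$carriers, "PS")
  expect_identical(rep$mild_only$gene, "GENEC")
  expect_identical(rep$mild_only$hgvs, "c.7C>T")   # the type-D row is ignored
  # shared variant appears in neither list
  expect_false("GENEB" %in% c(rep$severe_only$gene, rep$mild_only$gene))
})

test_that("identical variant sets yield empty family lists; unlabeled families are skipped", {
  ph <- make_phenotypes(c("A1", "A2"), family_id = "F2",
                        relative = c("REL_SEVERE", "REL_MILD"))
  v <- make_variant(gene = "GENEA", patient = c("A1", "A2"), af_exome = 0,
                    cadd = 25, hgvs = "c.1A>G")
  rep <- family_private_variants(v, ph, "F2")
  expect_equal(nrow(rep$severe_only), 0)
  expect_equal(nrow(rep$mild_only), 0)

  ph_bad <- make_phenotypes(c("B1", "B2"), family_id = "F3",
                            relative = c("REL_SEVERE", "NONE"))
  expect_warning(out <- family_private_variants(v, ph_bad, "F3"), "skipped")
  expect_null(out)
})

test_that("family reports are stable under reordering of variant rows", {
  fx <- family_fixture()
  r1 <- family_private_variants(fx$v, fx$ph, "F1")
  r2 <- family_private_variants(fx$v[rev(seq_len(nrow(fx$v))), ], fx$ph, "F1")
  expect_equal(r1, r2)
})

test_that("top variants split established vs candidate and apply the recessive rule", {
  reg <- small_registry()
  # GENEA established dominant; GENEB candidate recessive; GENEC candidate dominant
  v <- rbind(
    make_variant(gene = "GENEA", patient = "P1", af_exome = 0, cadd = 32,
                 hgvs = "est1"),
    make_variant(gene = "GENEB", patient = "P1", af_exome = 0, cadd = 35,
                 hgvs = "cand_recessive"),
    make_variant(gene = "GENEC", patient = "P1", af_exome = 0, cadd = 28,
                 hgvs = "cand_dominant"))
  rep <- top_variants_per_patient(v, "P1", reg)
  expect_identical(rep$established_top$gene, "GENEA")
  # candidate top CADD sits in a recessive gene; the dominant one is reported
  expect_identical(rep$candidate_top$gene, "GENEC")
  expect_true(rep$substitution_applied[["candidate"]])
  expect_false(rep$substitution_applied[["established"]])
})

test_that("recessive top is kept when no dominant-gene variant exists in the class", {
  reg <- small_registry()
  v <- make_variant(gene = "GENEB", patient = "P1", af_exome = 0, cadd = 35,
                    hgvs = "only_recessive")
  rep <- top_variants_per_patient(v, "P1", reg)
  expect_identical(rep$candidate_top$gene, "GENEB")
  expect_false(rep$substitution_applied[["candidate"]])
  expect_null(rep$established_top)   # Table-6 style dash
})

test_that("CADD ties break by lower frequency then gene symbol, independent of row order", {
  reg <- small_registry()
  v <- rbind(
    make_variant(gene = "GENEC", patient = "P1", af_exome = 0.005, cadd = 30,
                 hgvs = "tie_highaf"),
    make_variant(gene = "GENEB", patient = "P1", af_exome = 0.001, cadd = 30,
                 hgvs = "tie_lowaf"))
  rep <- top_variants_per_patient(v, "P1", reg)
  # GENEB wins the tie on lower max_af, but is recessive -> substitution
  expect_identical(rep$candidate_top$hgvs, "tie_highaf")
  expect_true(rep$substitution_applied[["candidate"]])
  rep2 <- top_variants_per_patient(v[2:1, ], "P1", reg)
  expect_equal(rep$candidate_top$hgvs, rep2$candidate_top$hgvs)
  # equal CADD and equal af: lexicographic gene symbol decides
  v3 <- rbind(
    make_variant(gene = "GENEC", patient = "P2", af_exome = 0.001, cadd = 30,
                 hgvs = "c_gene"),
    make_variant(gene = "GENEA", patient = "P2", af_exome = 0.001, cadd = 30,
                 hgvs = "a_gene"))
  rep3 <- top_variants_per_patient(v3, "P2", reg)
  expect_identical(rep3$established_top$hgvs, "a_gene")
})

test_that("every reported variant is category A", {
  reg <- small_registry()
  v <- rbind(
    make_variant(gene = "GENEA", patient = "P1", af_exome = 0.04, cadd = 39,
                 hgvs = "typeD_only"),
    make_variant(gene = "GENEA", patient = "P1", af_exome = 0.001, cadd = 21,
                 hgvs = "typeA"))
  rep <- top_variants_per_patient(v, "P1", reg)
  expect_identical(rep$established_top$hgvs, "typeA")
})

test_that("extreme report covers mild-restricted and sub-cutoff severe patients", {
  reg <- small_registry()
  ph <- make_phenotypes(c("P1", "P2", "P3"), lof = c(TRUE, FALSE, FALSE),
                        assessments = list(
                          assess(4, 90, 8, 80),    # mild LoF -> included
                          assess(4, 35, 8, 15),    # severe, score6 25 < 30
                          assess(4, 55, 8, 35)))   # severe, score6 45 >= 30
  v <- make_variant(gene = "GENEA", patient = c("P1", "P2", "P3"),
                    af_exome = 0, cadd = 25)
  rep <- extreme_variant_report(v, classify_cohort(ph), reg, iq_cutoff = 30)
  expect_setequal(unique(rep$patient_id), c("P1", "P2"))
  expect_setequal(unique(rep$class), c("established", "candidate"))
  # P1 has no candidate-gene variant: dash row with NA gene
  expect_true(is.na(rep$gene[rep$patient_id == "P1" & rep$class == "candidate"]))
})
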