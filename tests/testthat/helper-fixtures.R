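# Shared fixture builders and independent oracles.

# One-row (or stacked) variant table with sensible defaults.
make_variant <- function(gene = "EPI0002", patient = "P1",
                         af_exome = NA, af_genome = NA, cadd = 25,
                         consequence = "missense_variant", filter = "PASS",
                         hgvs = NULL, known_scn1a = FALSE) {
  n <- max(lengths(list(gene, patient, af_exome, af_genome, cadd,
                        consequence, filter, known_scn1a)))
  data.frame(patient_id = rep_len(as.character(patient), n),
             gene = rep_len(toupper(gene), n),
             consequence = rep_len(consequence, n),
             af_exome = rep_len(as.numeric(af_exome), n),
             af_genome = rep_len(as.numeric(af_genome), n),
             cadd_phred = rep_len(as.numeric(cadd), n),
             filter = rep_len(filter, n),
             hgvs = if (is.null(hgvs)) sprintf("c.%dA>G", seq_len(n))
                    else rep_len(hgvs, n),
             is_known_scn1a = rep_len(known_scn1a, n),
             stringsAsFactors = FALSE)
}

# Write gene lists (+ optional metadata) to a temp dir and load a registry.
make_registry <- function(lists, metadata = NULL) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- vapply(names(lists), function(s) {
    p <- file.path(d, paste0(s, ".txt"))
    writeLines(lists[[s]], p)
    p
  }, character(1))
  meta_path <- NULL
  if (!is.null(metadata)) {
    meta_path <- file.path(d, "meta.tsv")
    utils::write.table(metadata, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  load_registry(paths, metadata_file = meta_path)
}

# Small standard registry used across tests: EPILEPSY = {SCN1A, GENEA (est,
# dominant), GENEB (candidate, recessive), GENEC (candidate, dominant),
# GENEX (established, X-linked)}, CTRL1 = {CTL1A, CTL1B}, CTRL3 = {CTL3A},
# ID = {IDA}.
small_registry <- function(env = parent.frame()) {
  d <- withr::local_tempdir(.local_envir = env)
  lists <- list(EPILEPSY = c("SCN1A", "GENEA", "GENEB", "GENEC", "GENEX"),
                CTRL1 = c("CTL1A", "CTL1B"), CTRL3 = c("CTL3A"),
                ID = c("IDA"))
  paths <- vapply(names(lists), function(s) {
    p <- file.path(d, paste0(s, ".txt")); writeLines(lists[[s]], p); p
  }, character(1))
  meta <- data.frame(
    symbol = c("SCN1A", "GENEA", "GENEB", "GENEC", "GENEX", "CTL1A"),
    x_linked = c(0, 0, 0, 0, 1, 0),
    established = c(1, 1, 0, 0, 1, 0),
    inheritance = c("dominant", "dominant", "recessive", "dominant",
                    "x_linked", "unknown"))
  mp <- file.path(d, "meta.tsv")
  utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_registry(paths, metadata_file = mp)
}

# Phenotype-table row builder; assessments as list of age/score matrices.
make_phenotypes <- function(patient_id, sex = "FEMALE", family_id = NA,
                            current_age = 10, lof = FALSE,
                            relative = "NONE", assessments = list()) {
  n <- length(patient_id)
  df <- data.frame(patient_id = as.character(patient_id),
                   sex = rep_len(sex, n),
                   family_id = rep_len(family_id, n),
                   current_age = rep_len(current_age, n),
                   scn1a_lof_or_known_severe = rep_len(lof, n),
                   relative_severity = rep_len(relative, n),
                   stringsAsFactors = FALSE)
  if (length(assessments) == 0) {
    assessments <- replicate(n, matrix(c(5, 80), ncol = 2,
                                       dimnames = list(NULL, c("age", "score"))),
                             simplify = FALSE)
  }
  df$assessments <- assessments
  df
}

assess <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("age", "score")
  m
}

# Independent brute-force two-sided Fisher p (min-likelihood convention):
# enumerate the hypergeometric support directly via choose().
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || c2 == 0 || (c + d) == 0) return(1)
  xs <- max(0, r1 - c2):min(r1, c1)
  probs <- choose(c1, xs) * choose(c2, r1 - xs) / choose(n, r1)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Closed-form OLS prediction at age 6 (independent of stats::lm).
ols_at_six <- function(ages, scores) {
  b <- sum((ages - mean(ages)) * (scores - mean(scores))) /
    sum((ages - mean(ages))^2)
  (mean(scores) - b * mean(ages)) + 6 * b
}
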