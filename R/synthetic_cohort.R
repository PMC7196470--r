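#' Synthetic cohort generation with recorded ground truth
#'
#' Emulates the data-generating setting of an exome-sequenced SCN1A cohort:
#' 87 patients split into severity groups (29 mild of whom 10 carry a
#' LoF-class SCN1A variant, 22 severe, 18 intermediate, 18 unclassified),
#' per-patient-per-gene qualifying variant counts drawn from a Poisson whose
#' rate may be multiplied per (gene set, patient group), population
#' frequencies drawn from a mixture of strata spanning the A-E thresholds,
#' gamma-distributed CADD-PHRED scores, X-linked genes emitting at half
#' rate in males, declining linear IQ/DQ trajectories built to each
#' patient's severity band, and reference counts drawn from the same
#' frequency mixture. The generator returns the exact tables the analysis
#' modules consume plus a ground-truth record (planted multipliers,
#' independently derived category counts, true scores at age six).
#'
#' @name synthetic_cohort
NULL

#' Build a synthetic gene registry in memory
#'
#' Deterministic (RNG-free) registry with the requested set sizes.
#' Epilepsy symbols are EPI0001..., controls IMM/CVD/KID/HEM, ID genes IDG;
#' the real anchor SCN1A replaces the first epilepsy symbol. Every 20th
#' gene of a set is X-linked; the first `established_fraction` of the
#' epilepsy panel is flagged established; inheritance cycles
#' dominant/recessive/unknown (X-linked genes get X_LINKED).
#'
#' @param sizes named integer vector of set sizes.
#' @param established_fraction fraction of the epilepsy panel flagged as
#'   established diagnostic genes.
#' @param x_every one gene in every `x_every` is X-linked.
#' @return a `gene_registry`.
#' @export
synthetic_registry <- function(sizes = c(EPILEPSY = 422, CTRL1 = 360,
                                         CTRL2 = 109, CTRL3 = 223,
                                         CTRL4 = 297, ID = 659),
                               established_fraction = 0.4, x_every = 20L) {
  stopifnot(all(names(sizes) %in% GENE_SETS))
  prefix <- c(EPILEPSY = "EPI", CTRL1 = "IMM", CTRL2 = "CVD",
              CTRL3 = "KID", CTRL4 = "HEM", ID = "IDG")
  per_set <- lapply(names(sizes), function(s) {
    sym <- sprintf("%s%04d", prefix[[s]], seq_len(sizes[[s]]))
    if (s == "EPILEPSY") sym[1] <- "SCN1A"
    sym
  })
  names(per_set) <- names(sizes)
  symbols <- unlist(per_set, use.names = FALSE)
  membership <- vapply(GENE_SETS, function(s) {
    symbols %in% (per_set[[s]] %||% character())
  }, logical(length(symbols)))
  ord <- order(symbols)
  symbols <- symbols[ord]
  membership <- membership[ord, , drop = FALSE]
  rownames(membership) <- symbols

  x_linked <- logical(length(symbols))
  inheritance <- character(length(symbols))
  established <- logical(length(symbols))
  for (s in names(per_set)) {
    sym <- per_set[[s]]
    idx <- match(sym, symbols)
    within <- seq_along(sym)
    xl <- within %% x_every == 0L
    x_linked[idx] <- xl
    inh <- c("DOMINANT", "RECESSIVE", "UNKNOWN")[(within %% 3L) + 1L]
    inh[xl] <- "X_LINKED"
    inheritance[idx] <- inh
    if (s == "EPILEPSY") {
      established[idx] <- within <= round(established_fraction * length(sym))
    }
  }
  # SCN1A itself: autosomal dominant, established
  i <- match("SCN1A", symbols)
  x_linked[i] <- FALSE
  inheritance[i] <- "DOMINANT"
  established[i] <- TRUE

  structure(list(genes = data.frame(symbol = symbols, x_linked = x_linked,
                                    established = established,
                                    inheritance = inheritance,
                                    stringsAsFactors = FALSE),
                 membership = membership,
                 set_sizes = colSums(membership)),
            class = "gene_registry")
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 87 patients (29 mild / 22 severe /
#' 18 intermediate / 18 unclassified, 10 of the mild carrying a LoF-class
#' SCN1A variant), a qualifying-variant rate of 0.084 per patient per gene,
#' frequency-stratum weights chosen so that roughly 35% of sub-0.1 variants
#' are below MAF 0.01 and 76% below 0.05 (the cohort's C:D:E proportions),
#' and a gamma CADD distribution (shape 7, scale 3) placing about half the
#' mass above PHRED 20. `enrichment` is a named list: per gene set, a named
#' multiplier vector over groups (`MILD_RESTRICTED`, `SEVERE`,
#' `INTERMEDIATE`, `UNCLASSIFIED`, or `EXTREME` covering mild-restricted
#' and severe together).
#'
#' @param seed integer RNG seed; all randomness derives from it.
#' @param n_patients cohort size.
#' @param group_sizes named vector (MILD, SEVERE, INTERMEDIATE,
#'   UNCLASSIFIED) summing to at most `n_patients`.
#' @param n_mild_lof number of mild patients flagged LoF-class.
#' @param male_fraction probability a patient is male.
#' @param registry a `gene_registry`; default [synthetic_registry()].
#' @param per_gene_rate mean qualifying variants per patient per gene.
#' @param maf_weights weights of the five frequency strata: absent from the
#'   reference, (0, 0.01), \[0.01, 0.05), \[0.05, 0.1), \[0.1, 0.5\].
#' @param cadd_shape,cadd_scale gamma parameters of the CADD-PHRED score.
#' @param cadd_na_fraction fraction of variants with missing CADD.
#' @param enrichment named list of per-set multiplier vectors (see above).
#' @param reference_scale expected reference variants per gene across all
#'   strata.
#' @param n_families number of two-member families labelled with relative
#'   severities.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed,
                              n_patients = 87L,
                              group_sizes = c(MILD = 29L, SEVERE = 22L,
                                              INTERMEDIATE = 18L,
                                              UNCLASSIFIED = 18L),
                              n_mild_lof = 10L,
                              male_fraction = 0.5,
                              registry = NULL,
                              per_gene_rate = 0.084,
                              maf_weights = c(0.08, 0.20, 0.33, 0.19, 0.20),
                              cadd_shape = 7, cadd_scale = 3,
                              cadd_na_fraction = 0.02,
                              enrichment = list(),
                              reference_scale = 500,
                              n_families = 6L) {
  stopifnot(sum(group_sizes) <= n_patients,
            n_mild_lof <= group_sizes[["MILD"]],
            length(maf_weights) == 5, all(maf_weights >= 0),
            per_gene_rate >= 0, reference_scale > 0)
  if (length(enrichment)) {
    stopifnot(all(unlist(enrichment) > 0))
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 group_sizes = group_sizes, n_mild_lof = as.integer(n_mild_lof),
                 male_fraction = male_fraction, registry = registry,
                 per_gene_rate = per_gene_rate,
                 maf_weights = maf_weights / sum(maf_weights),
                 cadd_shape = cadd_shape, cadd_scale = cadd_scale,
                 cadd_na_fraction = cadd_na_fraction,
                 enrichment = enrichment,
                 reference_scale = reference_scale,
                 n_families = as.integer(n_families)),
            class = "sim_config")
}

# Stratum -> category membership, independent of the filtering module:
# category C = strata 1-2, D = 1-3, E = 1-4 (stratum 5 is MAF >= 0.1).
STRATUM_MAX_E <- 4L

sim_group_of <- function(config) {
  gs <- config$group_sizes
  sev <- rep(c("MILD", "SEVERE", "INTERMEDIATE", "UNCLASSIFIED", "NONE"),
             c(gs[["MILD"]], gs[["SEVERE"]], gs[["INTERMEDIATE"]],
               gs[["UNCLASSIFIED"]], config$n_patients - sum(gs)))
  lof <- logical(config$n_patients)
  lof[seq_len(config$n_mild_lof)] <- TRUE  # first mild patients
  list(severity = sev, lof = lof)
}

# Effective analysis-group label used for enrichment lookup.
enrichment_multiplier <- function(enrich_set, severity, lof) {
  if (is.null(enrich_set)) return(rep(1, length(severity)))
  grp <- ifelse(severity == "MILD" & lof, "MILD_RESTRICTED", severity)
  extreme <- grp %in% c("MILD_RESTRICTED", "SEVERE")
  m <- rep(1, length(severity))
  if ("EXTREME" %in% names(enrich_set)) {
    m[extreme] <- m[extreme] * enrich_set[["EXTREME"]]
  }
  for (g in setdiff(names(enrich_set), "EXTREME")) {
    m[grp == g] <- m[grp == g] * enrich_set[[g]]
  }
  m
}

#' Generate a synthetic cohort
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list with `variants` (data.frame in the variant-table dialect),
#'   `phenotypes` (phenotype dialect, assessments as list-column),
#'   `reference` (reference-count data.frame), and `truth` (ground-truth
#'   record: per-patient group and score at six, planted multipliers, and
#'   category counts per set/group derived directly from the simulation
#'   strata).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  registry <- config$registry %||% synthetic_registry()

  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))
  asg <- sim_group_of(config)
  sex <- ifelse(stats::runif(n) < config$male_fraction, "MALE", "FEMALE")

  genes <- registry$genes$symbol
  g_set <- apply(registry$membership, 1L, function(r) GENE_SETS[which(r)[1]])
  g_x <- registry$genes$x_linked

  # rate matrix (gene x patient), vectorized by column blocks
  base <- rep(config$per_gene_rate, length(genes))
  set_mult <- matrix(1, nrow = length(genes), ncol = n)
  for (s in unique(g_set)) {
    m_pat <- enrichment_multiplier(config$enrichment[[s]], asg$severity,
                                   asg$lof)
    set_mult[g_set == s, ] <- matrix(m_pat, nrow = sum(g_set == s),
                                     ncol = n, byrow = TRUE)
  }
  x_mult <- matrix(1, nrow = length(genes), ncol = n)
  x_mult[g_x, sex == "MALE"] <- 0.5  # one X in males
  lambda <- base * set_mult * x_mult

  k <- stats::rpois(length(lambda), lambda)
  dim(k) <- dim(lambda)
  idx <- which(k > 0, arr.ind = TRUE)
  reps <- k[k > 0]
  gene_i <- rep(idx[, 1], reps)
  pat_i <- rep(idx[, 2], reps)
  nv <- length(gene_i)

  stratum <- sample.int(5L, nv, replace = TRUE, prob = config$maf_weights)
  lo <- c(0, 0, 0.01, 0.05, 0.1)[stratum]
  hi <- c(0, 0.01, 0.05, 0.1, 0.5)[stratum]
  af_ex <- lo + (hi - lo) * stats::runif(nv)
  af_ge <- af_ex * stats::runif(nv)   # genome AF never exceeds exome AF here
  af_ex[stratum == 1L] <- NA_real_    # absent from the reference resource
  af_ge[stratum == 1L] <- NA_real_
  cadd <- stats::rgamma(nv, shape = config$cadd_shape,
                        scale = config$cadd_scale)
  cadd[stats::runif(nv) < config$cadd_na_fraction] <- NA_real_
  consequence <- sample(c("missense_variant", "frameshift_variant",
                          "stop_gained", "splice_donor_variant",
                          "inframe_deletion"),
                        nv, replace = TRUE,
                        prob = c(0.85, 0.05, 0.04, 0.03, 0.03))

  variants <- data.frame(
    patient_id = pid[pat_i],
    gene = genes[gene_i],
    consequence = consequence,
    af_exome = af_ex,
    af_genome = af_ge,
    cadd_phred = cadd,
    filter = "PASS",
    hgvs = sprintf("c.%dA>G", seq_len(nv)),
    is_known_scn1a = FALSE,
    stringsAsFactors = FALSE)

  # each patient's known pathogenic SCN1A call, excluded by filtering
  if ("SCN1A" %in% genes) {
    known <- data.frame(
      patient_id = pid, gene = "SCN1A", consequence = "missense_variant",
      af_exome = NA_real_, af_genome = NA_real_, cadd_phred = 28,
      filter = "PASS", hgvs = sprintf("c.%dT>C", 5000L + seq_len(n)),
      is_known_scn1a = TRUE, stringsAsFactors = FALSE)
    variants <- rbind(variants, known)
  }

  phen <- sim_phenotypes(config, pid, sex, asg)

  reference <- sim_reference(config, registry)

  truth <- list(
    config = config,
    patients = data.frame(patient_id = pid, sex = sex,
                          severity = asg$severity,
                          scn1a_lof_or_known_severe = asg$lof,
                          score6 = phen$true_score6,
                          stringsAsFactors = FALSE),
    category_counts = sim_truth_counts(g_set[gene_i], asg$severity[pat_i],
                                       asg$lof[pat_i], stratum, cadd),
    enrichment = config$enrichment)

  list(variants = variants, phenotypes = phen$table, reference = reference,
       truth = truth)
}

# Category counts computed straight from the simulation strata (independent
# of the filtering module's max_af arithmetic).
sim_truth_counts <- function(v_set, v_sev, v_lof, stratum, cadd) {
  grp <- ifelse(v_sev == "MILD" & v_lof, "MILD_RESTRICTED", v_sev)
  in_cat <- list(A = stratum <= 2L & !is.na(cadd) & cadd > 20,
                 B = stratum <= 2L & !is.na(cadd) & cadd > 10,
                 C = stratum <= 2L,
                 D = stratum <= 3L,
                 E = stratum <= STRATUM_MAX_E)
  rows <- list()
  groups <- list(MILD_RESTRICTED = "MILD_RESTRICTED", SEVERE = "SEVERE",
                 INTERMEDIATE = "INTERMEDIATE",
                 EXTREME = c("MILD_RESTRICTED", "SEVERE"),
                 COMPLETE = unique(grp))
  for (s in unique(v_set)) {
    for (g in names(groups)) {
      sel_g <- v_set == s & grp %in% groups[[g]]
      for (cat in names(in_cat)) {
        rows[[length(rows) + 1L]] <-
          data.frame(set = s, category = cat, group = g,
                     count = sum(sel_g & in_cat[[cat]]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

sim_phenotypes <- function(config, pid, sex, asg) {
  n <- config$n_patients
  score6 <- numeric(n)
  current_age <- numeric(n)
  assessments <- vector("list", n)
  unclass_seen <- 0L
  for (i in seq_len(n)) {
    sev <- asg$severity[i]
    if (sev == "MILD") {
      score6[i] <- stats::runif(1, 72, 100)
      current_age[i] <- stats::runif(1, 7, 20)
    } else if (sev == "SEVERE") {
      score6[i] <- stats::runif(1, 15, 48)
      current_age[i] <- stats::runif(1, 7, 20)
    } else if (sev == "INTERMEDIATE") {
      score6[i] <- stats::runif(1, 51, 69)
      current_age[i] <- stats::runif(1, 7, 20)
    } else {
      unclass_seen <- unclass_seen + 1L
      if (unclass_seen %% 2L == 0L) {
        # older patient without usable assessments
        score6[i] <- NA_real_
        current_age[i] <- stats::runif(1, 7, 20)
        assessments[[i]] <- matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("age", "score")))
        next
      }
      # under six, still above the severe bound
      score6[i] <- stats::runif(1, 55, 95)
      current_age[i] <- stats::runif(1, 2.5, 5.5)
    }
    # noiseless declining line through (6, score6)
    max_slope <- min(3, (score6[i] - 5) / 3)
    b <- -stats::runif(1, 0.2, max(0.21, max_slope))
    a <- score6[i] - 6 * b
    if (current_age[i] < 6) {
      ages <- sort(stats::runif(2, 1.5, current_age[i]))
    } else {
      ages <- sort(stats::runif(sample(2:4, 1), 3, 9))
    }
    ages <- round(ages, 2)
    while (anyDuplicated(ages)) ages <- ages + 0.01 * seq_along(ages)
    assessments[[i]] <- cbind(age = ages, score = a + b * ages)
  }

  family_id <- rep(NA_character_, n)
  relative <- rep("NONE", n)
  nf <- min(config$n_families, floor(n / 2))
  if (nf > 0) {
    for (f in seq_len(nf)) {
      i1 <- 2L * f - 1L; i2 <- 2L * f
      family_id[c(i1, i2)] <- sprintf("F%02d", f)
      relative[i1] <- "REL_SEVERE"
      relative[i2] <- "REL_MILD"
    }
  }

  table <- data.frame(patient_id = pid, sex = sex, family_id = family_id,
                      current_age = current_age,
                      scn1a_lof_or_known_severe = asg$lof,
                      relative_severity = relative,
                      stringsAsFactors = FALSE)
  table$assessments <- assessments
  list(table = table, true_score6 = score6)
}

sim_reference <- function(config, registry) {
  sets <- names(registry$set_sizes)[registry$set_sizes > 0]
  rows <- list()
  for (s in sets) {
    ng <- registry$set_sizes[[s]]
    per_stratum <- stats::rpois(4L, ng * config$reference_scale *
                                  config$maf_weights[1:4])
    cum <- cumsum(per_stratum)
    rows[[s]] <- data.frame(set = s,
                            maf_threshold = c(0.01, 0.05, 0.1),
                            count = cum[2:4],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
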