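#' Variant filtering and A-E categorisation
#'
#' Qualifying variants are PASS calls whose predicted consequence alters the
#' protein (frameshift, stop gain/loss, start loss, in-frame indel, splice
#' donor/acceptor, missense), excluding each patient's known pathogenic
#' SCN1A variant. Qualifying variants are then placed in nested categories
#' by population frequency and CADD deleteriousness:
#'
#' * type A: MAF < 0.01 in both exomes and genomes, CADD-PHRED > 20
#' * type B: MAF < 0.01, CADD-PHRED > 10
#' * type C: MAF < 0.01, any CADD
#' * type D: MAF < 0.05
#' * type E: MAF < 0.1
#'
#' "MAF below the threshold in both exomes and genomes" is implemented as
#' `max(af_exome, af_genome) < threshold`; a variant absent from one
#' resource contributes 0 for that resource. MAF bounds are strict `<`,
#' CADD bounds strict `>`. A missing CADD score disqualifies only A and B.
#'
#' @name variant_filtering
NULL

VARIANT_CATEGORIES <- c("A", "B", "C", "D", "E")
CATEGORY_MAF <- c(A = 0.01, B = 0.01, C = 0.01, D = 0.05, E = 0.1)
CATEGORY_CADD <- c(A = 20, B = 10, C = -Inf, D = -Inf, E = -Inf)

# Canonical Sequence-Ontology-style consequence whitelist.
CONSEQUENCE_WHITELIST <- c(
  "frameshift_variant", "stop_gained", "stop_lost", "start_lost",
  "inframe_deletion", "inframe_insertion",
  "splice_donor_variant", "splice_acceptor_variant", "missense_variant"
)

# Synonyms seen in annotation exports, mapped onto the canonical terms.
CONSEQUENCE_SYNONYMS <- c(
  "frameshift"                 = "frameshift_variant",
  "stop-gain"                  = "stop_gained",
  "stop_gain"                  = "stop_gained",
  "stopgain"                   = "stop_gained",
  "nonsense"                   = "stop_gained",
  "stop-loss"                  = "stop_lost",
  "stop_loss"                  = "stop_lost",
  "stoploss"                   = "stop_lost",
  "start-loss"                 = "start_lost",
  "start_loss"                 = "start_lost",
  "startloss"                  = "start_lost",
  "in-frame deletion"          = "inframe_deletion",
  "in_frame_deletion"          = "inframe_deletion",
  "inframe deletion"           = "inframe_deletion",
  "in-frame insertion"         = "inframe_insertion",
  "in_frame_insertion"         = "inframe_insertion",
  "inframe insertion"          = "inframe_insertion",
  "splice donor"               = "splice_donor_variant",
  "splice_donor"               = "splice_donor_variant",
  "splice acceptor"            = "splice_acceptor_variant",
  "splice_acceptor"            = "splice_acceptor_variant",
  "missense"                   = "missense_variant",
  "nonsynonymous missense"     = "missense_variant",
  "nonsynonymous_missense"     = "missense_variant",
  "nonsynonymous snv"          = "missense_variant"
)

# Non-qualifying but recognised terms: excluded silently (not unknown).
CONSEQUENCE_KNOWN_OTHER <- c(
  "synonymous_variant", "synonymous", "intron_variant", "intron",
  "intergenic_variant", "utr_variant", "5_prime_utr_variant",
  "3_prime_utr_variant", "upstream_gene_variant", "downstream_gene_variant",
  "splice_region_variant", "non_coding_transcript_variant"
)

normalize_consequence <- function(x) {
  x0 <- tolower(trimws(x))
  mapped <- CONSEQUENCE_SYNONYMS[x0]
  out <- ifelse(is.na(mapped), x0, mapped)
  unname(out)
}

#' Read an annotated per-patient variant table
#'
#' Expected TSV columns: `patient_id`, `gene`, `consequence`, `af_exome`,
#' `af_genome`, `cadd_phred`, `filter`, `hgvs`, `is_known_scn1a` (0/1).
#' Empty strings denote missing values. Allele frequencies must lie in
#' \[0, 1\] and CADD scores must be non-negative when present.
#'
#' @param path path to the TSV file.
#' @return data.frame with normalised column types; gene symbols upper-cased.
#' @export
read_variants <- function(path) {
  df <- read_tsv_strict(path,
                        required = c("patient_id", "gene", "consequence",
                                     "af_exome", "af_genome", "cadd_phred",
                                     "filter", "hgvs", "is_known_scn1a"),
                        numeric_cols = c("af_exome", "af_genome", "cadd_phred"))
  df$patient_id <- as.character(df$patient_id)
  df$gene <- toupper(df$gene)
  df$is_known_scn1a <- as.logical(as.integer(df$is_known_scn1a))
  validate_variants(df)
  df
}

validate_variants <- function(df) {
  for (col in c("af_exome", "af_genome")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad)) {
      stop("variant table: ", col, " outside [0,1] at row ", bad[1],
           call. = FALSE)
    }
  }
  bad <- which(!is.na(df$cadd_phred) & df$cadd_phred < 0)
  if (length(bad)) {
    stop("variant table: negative cadd_phred at row ", bad[1], call. = FALSE)
  }
  invisible(df)
}

#' Does each variant qualify for analysis?
#'
#' TRUE iff the call is PASS, the consequence is on the protein-altering
#' whitelist, and the row is not the patient's known pathogenic SCN1A
#' variant. Consequence terms outside the recognised vocabulary are either
#' rejected with a warning (default) or raise an error.
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param on_unknown `"warn"` (exclude unknown consequence terms with a
#'   warning) or `"error"`.
#' @return logical vector, one element per row.
#' @export
qualifies <- function(variants, on_unknown = c("warn", "error")) {
  on_unknown <- match.arg(on_unknown)
  cons <- normalize_consequence(variants$consequence)
  known <- cons %in% c(CONSEQUENCE_WHITELIST, CONSEQUENCE_KNOWN_OTHER)
  if (any(!known)) {
    terms <- unique(variants$consequence[!known])
    msg <- paste0("unrecognized consequence term(s): ",
                  paste(utils::head(terms, 5), collapse = ", "),
                  if (length(terms) > 5) ", ..." else "")
    if (on_unknown == "error") stop(msg, call. = FALSE)
    warning(msg, " - excluded", call. = FALSE)
  }
  (variants$filter == "PASS") &
    (cons %in% CONSEQUENCE_WHITELIST) &
    !variants$is_known_scn1a
}

# max(af_exome, af_genome) with missing treated as 0 (absent from resource).
max_af <- function(variants) {
  pmax(ifelse(is.na(variants$af_exome), 0, variants$af_exome),
       ifelse(is.na(variants$af_genome), 0, variants$af_genome))
}

#' Category membership matrix for qualifying variants
#'
#' @param variants variant data.frame; rows are assumed to qualify
#'   (see [qualifies()]).
#' @return logical matrix with one row per variant and columns A-E. Because
#'   thresholds are nested, membership in A implies B implies C implies D
#'   implies E.
#' @export
category_matrix <- function(variants) {
  af <- max_af(variants)
  cadd <- variants$cadd_phred  # NA disqualifies A and B only
  m <- vapply(VARIANT_CATEGORIES, function(cat) {
    ok <- af < CATEGORY_MAF[[cat]]
    if (is.finite(CATEGORY_CADD[[cat]])) {
      ok <- ok & !is.na(cadd) & cadd > CATEGORY_CADD[[cat]]
    }
    ok
  }, logical(nrow(variants)))
  if (nrow(variants) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, VARIANT_CATEGORIES))
  m
}

#' Categories met by a single variant
#'
#' @param variant one-row variant data.frame.
#' @return character subset of `c("A","B","C","D","E")`.
#' @export
categories <- function(variant) {
  stopifnot(nrow(variant) == 1L)
  m <- category_matrix(variant)
  VARIANT_CATEGORIES[m[1, ]]
}

#' Count qualifying variants in a gene set, category, and patient subset
#'
#' Each variant row counts once regardless of zygosity. The gene set may be
#' `"CTRL1-4"` for the pooled controls.
#'
#' @param variants qualifying variant rows.
#' @param registry a `gene_registry`.
#' @param category one of `"A".."E"`.
#' @param set_name a registry set or `"CTRL1-4"`.
#' @param patients character vector of patient ids to include.
#' @param all_patients the universe of known patient ids; defaults to the
#'   ids present in `variants`. Ids in `patients` outside this universe are
#'   an error.
#' @return non-negative integer count.
#' @export
count_variants <- function(variants, registry, category, set_name, patients,
                           all_patients = unique(variants$patient_id)) {
  stopifnot(category %in% VARIANT_CATEGORIES)
  unknown <- setdiff(patients, all_patients)
  if (length(unknown)) {
    stop("unknown patient id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(variants) == 0L || length(patients) == 0L) return(0L)
  in_set <- variants$gene %in% genes_in_set(registry, set_name)
  in_cat <- category_matrix(variants)[, category]
  sum(in_set & in_cat & variants$patient_id %in% patients)
}

#' Read a reference (ExAC-style) variant-count summary
#'
#' TSV columns: `set`, `maf_threshold` (0.01 | 0.05 | 0.1), `count`. These
#' are the aggregate numbers of qualifying variants per gene set at each
#' frequency threshold in the reference population, taken as given.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns set, maf_threshold, count.
#' @export
read_reference_counts <- function(path) {
  df <- read_tsv_strict(path, required = c("set", "maf_threshold", "count"),
                        numeric_cols = c("maf_threshold", "count"))
  if (any(df$count < 0)) stop("reference counts must be non-negative", call. = FALSE)
  df
}
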