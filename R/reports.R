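#' Descriptive variant reports
#'
#' Two descriptive outputs complement the statistical comparisons. In
#' families whose members share the same pathogenic SCN1A variant but show
#' clearly different severities, type-A variants carried only by the
#' relatively severe members (candidate aggravating modifiers) or only by
#' the relatively mild members (candidate protective modifiers) are listed.
#' For patients at the extremes of the spectrum, the predicted most
#' deleterious type-A variant (highest CADD) is reported separately for
#' established diagnostic epilepsy genes and for candidate genes, with a
#' substitution rule: when the top variant sits in a recessive gene and a
#' dominant-gene variant exists in the same class, the dominant one is
#' reported instead.
#'
#' @name descriptive_reports
NULL

# Restrict a qualifying variant table to category A rows.
category_a_rows <- function(variants) {
  variants[category_matrix(variants)[, "A"], , drop = FALSE]
}

#' Family-private type-A variants
#'
#' A variant (identified by gene + HGVS label) is "severe-only" when
#' carried by at least one relatively severe member and by no relatively
#' mild member; "mild-only" is symmetric. Variants carried by members of
#' both labels are excluded from both lists. Carrier ids are reported per
#' variant so nested sharing within a label is visible.
#'
#' @param variants qualifying variant rows (any categories; the report
#'   itself uses only type A).
#' @param phenotypes phenotype table with `patient_id`, `family_id` and
#'   `relative_severity` columns.
#' @param family_id the family to report.
#' @return list with `family_id`, `severe_only` and `mild_only`
#'   data.frames (gene, hgvs, max_af, cadd_phred, carriers).
#' @export
family_private_variants <- function(variants, phenotypes, family_id) {
  fam <- phenotypes[!is.na(phenotypes$family_id) &
                      phenotypes$family_id == family_id, ]
  mild_ids <- fam$patient_id[fam$relative_severity == "REL_MILD"]
  severe_ids <- fam$patient_id[fam$relative_severity == "REL_SEVERE"]
  if (length(mild_ids) == 0L || length(severe_ids) == 0L) {
    warning("family ", family_id,
            " lacks both REL_MILD and REL_SEVERE members; skipped",
            call. = FALSE)
    return(NULL)
  }
  va <- category_a_rows(variants)
  va <- va[va$patient_id %in% c(mild_ids, severe_ids), , drop = FALSE]
  key <- paste(va$gene, va$hgvs, sep = "|")
  per_side <- function(only_ids, other_ids) {
    in_only <- key %in% key[va$patient_id %in% only_ids]
    in_other <- key %in% key[va$patient_id %in% other_ids]
    sel <- unique(key[in_only & !in_other])
    if (length(sel) == 0L) {
      return(data.frame(gene = character(), hgvs = character(),
                        max_af = numeric(), cadd_phred = numeric(),
                        carriers = character(), stringsAsFactors = FALSE))
    }
    rows <- lapply(sel, function(k) {
      vi <- va[key == k, , drop = FALSE]
      data.frame(gene = vi$gene[1], hgvs = vi$hgvs[1],
                 max_af = max_af(vi)[1], cadd_phred = vi$cadd_phred[1],
                 carriers = paste(sort(unique(vi$patient_id)), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$gene, out$hgvs), ]
    rownames(out) <- NULL
    out
  }
  list(family_id = family_id,
       severe_only = per_side(severe_ids, mild_ids),
       mild_only = per_side(mild_ids, severe_ids))
}

#' Family reports for every eligible family
#'
#' @inheritParams family_private_variants
#' @return named list of [family_private_variants()] results, skipping
#'   families without both severity labels.
#' @export
family_reports <- function(variants, phenotypes) {
  fams <- unique(stats::na.omit(phenotypes$family_id))
  out <- list()
  for (f in fams) {
    rep <- family_private_variants(variants, phenotypes, f)
    if (!is.null(rep)) out[[as.character(f)]] <- rep
  }
  out
}

# Highest-CADD variant among rows, with deterministic tie-break:
# higher CADD first, then lower max_af, then lexicographic gene symbol,
# then lexicographic hgvs.
pick_top_cadd <- function(rows) {
  rows <- rows[!is.na(rows$cadd_phred), , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  af <- max_af(rows)
  ord <- order(-rows$cadd_phred, af, rows$gene, rows$hgvs)
  rows[ord[1], , drop = FALSE]
}

#' Most deleterious type-A variants of one patient
#'
#' Within each gene class of the epilepsy panel (established diagnostic
#' genes vs candidate genes), the highest-CADD type-A variant is selected.
#' If that variant's gene has recessive inheritance and the class also
#' contains a variant in a dominant gene, the highest-CADD dominant-gene
#' variant is reported instead and `substitution_applied` is set.
#'
#' @param variants qualifying variant rows of the whole cohort.
#' @param patient_id patient to report.
#' @param registry a `gene_registry`.
#' @return list with `patient_id`, `established_top`, `candidate_top`
#'   (one-row data.frames or NULL), and logical
#'   `substitution_applied` (per class, named vector).
#' @export
top_variants_per_patient <- function(variants, patient_id, registry) {
  va <- category_a_rows(variants)
  va <- va[va$patient_id == patient_id &
             va$gene %in% genes_in_set(registry, "EPILEPSY"), , drop = FALSE]
  est <- registry_lookup(registry, "established")
  inh <- registry_lookup(registry, "inheritance")
  pick_class <- function(class_rows) {
    top <- pick_top_cadd(class_rows)
    if (is.null(top)) return(list(top = NULL, substituted = FALSE))
    if (identical(unname(inh[[top$gene]]), "RECESSIVE")) {
      dom <- class_rows[inh[class_rows$gene] == "DOMINANT", , drop = FALSE]
      dom_top <- pick_top_cadd(dom)
      if (!is.null(dom_top)) return(list(top = dom_top, substituted = TRUE))
    }
    list(top = top, substituted = FALSE)
  }
  e <- pick_class(va[est[va$gene], , drop = FALSE])
  c_ <- pick_class(va[!est[va$gene], , drop = FALSE])
  list(patient_id = patient_id,
       established_top = e$top,
       candidate_top = c_$top,
       substitution_applied = c(established = e$substituted,
                                candidate = c_$substituted))
}

#' Extreme-patient top-variant report
#'
#' Reports [top_variants_per_patient()] for every extreme-phenotype
#' patient: all mild-restricted patients plus severe patients whose
#' interpolated score at six is below `iq_cutoff`.
#'
#' @param variants qualifying variant rows.
#' @param phenotypes classified phenotype table (with `score6`, `severity`).
#' @param registry a `gene_registry`.
#' @param iq_cutoff severe-side cutoff on the interpolated score (default 30).
#' @return data.frame with one row per patient and class (established /
#'   candidate): gene, hgvs, cadd_phred, max_af, substitution_applied.
#' @export
extreme_variant_report <- function(variants, phenotypes, registry,
                                   iq_cutoff = 30) {
  if (!"severity" %in% names(phenotypes)) {
    phenotypes <- classify_cohort(phenotypes)
  }
  groups <- analysis_groups(phenotypes)
  severe_extreme <- phenotypes$patient_id[
    phenotypes$severity == "SEVERE" & !is.na(phenotypes$score6) &
      phenotypes$score6 < iq_cutoff]
  ids <- c(groups$MILD_RESTRICTED, severe_extreme)
  rows <- lapply(ids, function(pid) {
    rep <- top_variants_per_patient(variants, pid, registry)
    side <- function(class, top, subst) {
      if (is.null(top)) {
        data.frame(patient_id = pid, class = class, gene = NA_character_,
                   hgvs = NA_character_, cadd_phred = NA_real_,
                   max_af = NA_real_, substitution_applied = subst,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(patient_id = pid, class = class, gene = top$gene,
                   hgvs = top$hgvs, cadd_phred = top$cadd_phred,
                   max_af = max_af(top), substitution_applied = subst,
                   stringsAsFactors = FALSE)
      }
    }
    rbind(side("established", rep$established_top,
               rep$substitution_applied[["established"]]),
          side("candidate", rep$candidate_top,
               rep$substitution_applied[["candidate"]]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), class = character(),
                      gene = character(), hgvs = character(),
                      cadd_phred = numeric(), max_af = numeric(),
                      substitution_applied = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
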