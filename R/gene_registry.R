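#' Gene set registry
#'
#' The analysis works on six panels of genes: the epilepsy panel (established
#' diagnostic genes plus candidate modifier genes), four control panels drawn
#' from unrelated disease areas (immunodeficiency, cardiovascular disease,
#' kidney disease, and a mixed haemostasis/membrane/diarrhea/erythroderma/
#' angioedema panel), and an intellectual-disability panel from which genes
#' shared with the epilepsy panel are removed. A registry holds, per gene,
#' its set memberships, X-linkage, whether it is an established diagnostic
#' epilepsy gene, and its inheritance mode.
#'
#' @name gene_registry
NULL

GENE_SETS <- c("EPILEPSY", "CTRL1", "CTRL2", "CTRL3", "CTRL4", "ID")
INHERITANCE_MODES <- c("DOMINANT", "RECESSIVE", "X_LINKED", "UNKNOWN")

#' Load a gene set registry from plain-text gene lists
#'
#' Each gene list file carries one gene symbol per line; `#` starts a
#' comment. Symbols are case-normalised to upper case. Genes present in both
#' the ID and EPILEPSY lists are dropped from ID (with a warning), because
#' the ID panel is defined net of epilepsy genes. Overlap between the
#' epilepsy panel and a control panel is permitted but reported, as is
#' overlap among control panels.
#'
#' @param gene_list_files named character vector of file paths; names must be
#'   a subset of `EPILEPSY, CTRL1, CTRL2, CTRL3, CTRL4, ID`.
#' @param metadata_file optional TSV with columns `symbol`, `x_linked` (0/1),
#'   `established` (0/1), `inheritance` (dominant|recessive|x_linked|unknown).
#'   Genes absent from the file default to non-X-linked, non-established,
#'   UNKNOWN inheritance.
#' @return a `gene_registry` object: a list with `genes` (data.frame of
#'   symbol, x_linked, established, inheritance), `membership` (logical
#'   matrix genes x sets) and `set_sizes` (named integer vector).
#' @export
load_registry <- function(gene_list_files, metadata_file = NULL) {
  if (is.null(names(gene_list_files)) || any(names(gene_list_files) == "")) {
    stop("gene_list_files must be a named vector (names are set names)",
         call. = FALSE)
  }
  unknown <- setdiff(names(gene_list_files), GENE_SETS)
  if (length(unknown)) {
    stop("unknown gene set name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lists <- lapply(gene_list_files, function(p) {
    if (!file.exists(p)) stop("gene list file does not exist: ", p, call. = FALSE)
    x <- readLines(p, warn = FALSE)
    x <- sub("#.*$", "", x)
    x <- trimws(x)
    unique(toupper(x[nzchar(x)]))
  })

  if (all(c("ID", "EPILEPSY") %in% names(lists))) {
    shared <- intersect(lists$ID, lists$EPILEPSY)
    if (length(shared)) {
      warning(length(shared), " gene(s) present in both ID and EPILEPSY lists ",
              "removed from ID: ", paste(utils::head(shared, 5), collapse = ", "),
              if (length(shared) > 5) ", ..." else "", call. = FALSE)
      lists$ID <- setdiff(lists$ID, lists$EPILEPSY)
    }
  }
  ctrl <- intersect(names(lists), paste0("CTRL", 1:4))
  if ("EPILEPSY" %in% names(lists)) {
    for (cs in ctrl) {
      ov <- intersect(lists$EPILEPSY, lists[[cs]])
      if (length(ov)) {
        message("note: ", length(ov), " gene(s) shared between EPILEPSY and ",
                cs, " (membership kept in both)")
      }
    }
  }

  symbols <- sort(unique(unlist(lists)))
  membership <- vapply(GENE_SETS, function(s) {
    symbols %in% (lists[[s]] %||% character())
  }, logical(length(symbols)))
  if (length(symbols) < 2L) {
    membership <- matrix(membership, nrow = length(symbols), ncol = length(GENE_SETS),
                         dimnames = list(NULL, GENE_SETS))
  }
  rownames(membership) <- symbols

  genes <- data.frame(symbol = symbols,
                      x_linked = FALSE,
                      established = FALSE,
                      inheritance = "UNKNOWN",
                      stringsAsFactors = FALSE)
  if (!is.null(metadata_file)) {
    meta <- read_tsv_strict(metadata_file,
                            required = c("symbol", "x_linked", "established",
                                         "inheritance"))
    meta$symbol <- toupper(meta$symbol)
    meta$inheritance <- toupper(meta$inheritance)
    bad_inh <- setdiff(unique(meta$inheritance), INHERITANCE_MODES)
    if (length(bad_inh)) {
      stop("unknown inheritance mode(s) in metadata: ",
           paste(bad_inh, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(meta$symbol)) {
      dup <- unique(meta$symbol[duplicated(meta$symbol)])
      conflict <- vapply(dup, function(s) {
        rows <- meta[meta$symbol == s, c("x_linked", "established", "inheritance")]
        nrow(unique(rows)) > 1
      }, logical(1))
      if (any(conflict)) {
        stop("conflicting metadata for duplicated symbol(s): ",
             paste(dup[conflict], collapse = ", "), call. = FALSE)
      }
      meta <- meta[!duplicated(meta$symbol), ]
    }
    idx <- match(genes$symbol, meta$symbol)
    hit <- !is.na(idx)
    genes$x_linked[hit] <- as.logical(as.integer(meta$x_linked[idx[hit]]))
    genes$established[hit] <- as.logical(as.integer(meta$established[idx[hit]]))
    genes$inheritance[hit] <- meta$inheritance[idx[hit]]
  }

  structure(list(genes = genes,
                 membership = membership,
                 set_sizes = colSums(membership)),
            class = "gene_registry")
}

#' @export
print.gene_registry <- function(x, ...) {
  cat("gene_registry:", nrow(x$genes), "genes\n")
  sz <- x$set_sizes
  cat(paste0("  ", names(sz), ": ", sz, collapse = "\n"), "\n")
  invisible(x)
}

#' Set memberships of one gene symbol
#'
#' @param registry a `gene_registry`.
#' @param symbol a single gene symbol (case-insensitive).
#' @return character vector of set names; empty if the gene is absent.
#' @export
membership <- function(registry, symbol) {
  stopifnot(inherits(registry, "gene_registry"), length(symbol) == 1L)
  row <- match(toupper(symbol), rownames(registry$membership))
  if (is.na(row)) return(character())
  names(which(registry$membership[row, ]))
}

#' Gene symbols belonging to a set (or the pooled controls)
#'
#' `set_name = "CTRL1-4"` returns the union of the four control panels.
#'
#' @inheritParams membership
#' @param set_name one of the registry sets or `"CTRL1-4"`.
#' @return character vector of symbols.
#' @export
genes_in_set <- function(registry, set_name) {
  stopifnot(inherits(registry, "gene_registry"))
  if (set_name == "CTRL1-4") {
    keep <- rowSums(registry$membership[, paste0("CTRL", 1:4), drop = FALSE]) > 0
  } else {
    if (!set_name %in% GENE_SETS) {
      stop("unknown gene set: ", set_name, call. = FALSE)
    }
    keep <- registry$membership[, set_name]
  }
  rownames(registry$membership)[keep]
}

# Fast lookup vectors used by the counting code.
registry_lookup <- function(registry, field) {
  stats::setNames(registry$genes[[field]], registry$genes$symbol)
}

#' The bundled synthetic fixture registry
#'
#' Loads the gene lists shipped with the package. The lists use synthetic
#' symbols (plus the real anchor SCN1A in the epilepsy panel) but reproduce
#' the panel sizes of the study design: epilepsy 422, control panels
#' 360/109/223/297, ID 659.
#'
#' @return a `gene_registry`.
#' @export
fixture_registry <- function() {
  d <- system.file("extdata", package = "modburden")
  files <- c(EPILEPSY = "genes_epilepsy.txt", CTRL1 = "genes_ctrl1.txt",
             CTRL2 = "genes_ctrl2.txt", CTRL3 = "genes_ctrl3.txt",
             CTRL4 = "genes_ctrl4.txt", ID = "genes_id.txt")
  load_registry(stats::setNames(file.path(d, files), names(files)),
                metadata_file = file.path(d, "gene_metadata.tsv"))
}
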