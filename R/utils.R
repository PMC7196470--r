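#' @keywords internal
"_PACKAGE"

# Rounding convention used for displayed percentages: ties away from zero.
# base::round() rounds half to even, which would turn 37.5 into 38 but 36.5
# into 36; tables here follow the away-from-zero convention instead.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a TSV with stringent defaults shared by all table readers.
read_tsv_strict <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(val))
    if (length(bad)) {
      stop("file ", path, ", column '", col, "', line ", bad[1] + 1,
           ": not a number: '", df[[col]][bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- val
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
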