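# Readers/writers for the plain-text formats used throughout: genes x samples
# TSV matrices ("NA" for missing), covariate tables, GMT gene-set files,
# two-column complex membership tables and scored edge lists.

#' Read a genes x samples omics matrix from TSV
#'
#' Expects a header row of sample identifiers, the first column holding gene
#' identifiers, and literal `NA` for missing entries.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_omics <- function(path) {
  # base parser: strtod is correctly rounded, so written doubles round-trip
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "gene_id") abort("omics TSV needs a `gene_id` first column")
  if (anyDuplicated(df[[1]])) abort("omics TSV has duplicated gene ids")
  m <- vapply(df[-1], as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)[-1]))
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_omics
#' @param m Numeric genes x samples matrix with dimnames.
#' @export
write_omics <- function(m, path) {
  check_omics_matrix(m)
  # %.17g guarantees bit-exact round trips for doubles (shortest readr output
  # does not)
  fmt <- matrix(sprintf("%.17g", m), nrow(m))
  fmt[is.na(m)] <- "NA"
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(fmt, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT semantics: one set per line, tab-separated `name`, `description`,
#' then member identifiers. Duplicated members within a set are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions kept as an attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) abort(sprintf("GMT line(s) %s have fewer than 3 fields",
                              paste(which(bad), collapse = ", ")))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column complex membership table
#'
#' @param path TSV with columns `complex_id`, `gene_id` (CORUM-like long
#'   format: one row per subunit).
#' @return Tibble with those two columns.
#' @export
read_complexes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    complex_id = readr::col_character(), gene_id = readr::col_character()))
}

#' Read a covariate table
#'
#' @param path TSV with a `sample_id` column plus covariates (continuous
#'   `age`; categorical `gender`, `tumour_type`, `technology`, ...).
#' @return Tibble, one row per sample.
#' @export
read_covariates <- function(path) {
  cov <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(cov)) abort("covariate table needs a `sample_id` column")
  if (anyDuplicated(cov$sample_id)) abort("covariate table has duplicated sample ids")
  cov
}

#' Read a scored edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b` and optionally `score`
#'   (STRING-like functional edges or kinase-substrate pairs).
#' @return Tibble.
#' @export
read_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
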