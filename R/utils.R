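# Shared numeric helpers: pairwise-complete Pearson, rank-sum AROC, and small
# validators used across the analysis stages.

#' Pairwise-complete Pearson correlation
#'
#' Correlation between two vectors using only positions where both are finite.
#' Returns `NA` (with the number of complete pairs) when fewer than `min_obs`
#' pairs remain or either vector is constant on the complete pairs.
#'
#' @param x,y Numeric vectors of equal length; `NA`s allowed.
#' @param min_obs Minimum number of complete pairs required for a finite r.
#' @return A list with elements `r` and `n`.
#' @export
pearson_pairwise <- function(x, y, min_obs = 3L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < max(3L, min_obs)) {
    return(list(r = NA_real_, n = n))
  }
  xs <- x[ok]
  ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) {
    return(list(r = NA_real_, n = n))
  }
  list(r = cor(xs, ys), n = n)
}

#' Area under the ROC curve by the rank-sum identity
#'
#' AROC equals the probability that a randomly chosen positive outranks a
#' randomly chosen negative (Mann-Whitney); ties contribute 1/2 via midranks.
#'
#' @param score Numeric classifier score (higher = more positive).
#' @param is_positive Logical labels, same length as `score`.
#' @return AROC in `[0, 1]`.
#' @export
aroc <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive), is.logical(is_positive))
  keep <- is.finite(score)
  score <- score[keep]
  is_positive <- is_positive[keep]
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L) {
    abort("aroc() needs at least one positive and one negative with finite scores")
  }
  r <- rank(score)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Number of unique pairwise coefficients for a gene universe
#'
#' The pair-count identity for all-against-all correlation analyses:
#' `n_levels * choose(n_genes, 2)` unordered gene pairs.
#'
#' @param n_genes Number of genes correlated at each molecular level.
#' @param n_levels Number of molecular levels (e.g. protein and transcript).
#' @return Integer-valued count (as double to avoid 32-bit overflow).
#' @export
n_pairwise_coefficients <- function(n_genes, n_levels = 2) {
  stopifnot(n_genes >= 2, n_levels >= 1)
  n_levels * choose(n_genes, 2)
}

# Validate a genes x samples matrix with dimnames; returns invisibly.
check_omics_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must carry gene rownames and sample colnames", arg))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("`%s` has duplicated gene identifiers", arg))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` has duplicated sample identifiers", arg))
  }
  invisible(m)
}

# Align matrices on the intersection of genes and samples, preserving the
# order of the first matrix.
align_matrices <- function(...) {
  ms <- list(...)
  lapply(ms, check_omics_matrix)
  genes <- Reduce(intersect, lapply(ms, rownames))
  samples <- Reduce(intersect, lapply(ms, colnames))
  if (length(genes) == 0L) abort("no genes shared across matrices")
  if (length(samples) == 0L) abort("no samples shared across matrices")
  lapply(ms, function(m) m[genes, samples, drop = FALSE])
}

# Canonical unordered pair key "a|b" with a < b lexicographically.
pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  paste(a, b, sep = "\r")
}
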