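# Preprocessing: CPM expression filter, proteome coverage, linear-model
# confounder removal, presence filtering and KDE-mode centering.

#' Filter lowly expressed genes and return log2-CPM
#'
#' Computes counts-per-million per sample, removes genes whose mean CPM across
#' samples is at or below `min_mean_cpm`, and returns `log2(CPM + 0.5)` for
#' the surviving genes. Library sizes are the full-column sums before
#' filtering.
#'
#' @param counts Non-negative integer genes x samples matrix with dimnames.
#' @param min_mean_cpm Exclusion threshold on the mean CPM (default 1; the
#'   filter is strict: mean CPM equal to the threshold is excluded).
#' @return log2-CPM matrix for retained genes, sample order unchanged.
#' @export
cpm_filter_log <- function(counts, min_mean_cpm = 1) {
  check_omics_matrix(counts, "counts")
  if (any(counts < 0, na.rm = TRUE)) abort("`counts` must be non-negative")
  libsize <- colSums(counts)
  if (any(libsize <= 0)) {
    abort(sprintf("zero library size for sample(s): %s",
                  paste(colnames(counts)[libsize <= 0], collapse = ", ")))
  }
  cpm <- sweep(counts, 2, libsize, "/") * 1e6
  keep <- rowMeans(cpm) > min_mean_cpm
  log2(cpm[keep, , drop = FALSE] + 0.5)
}

#' Proteome coverage of the expressed transcriptome (Jaccard index)
#'
#' Intersection over union of the expressed-gene set and the measured-protein
#' set for one sample.
#'
#' @param expressed,measured Character vectors of gene identifiers.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_jaccard <- function(expressed, measured) {
  expressed <- unique(expressed)
  measured <- unique(measured)
  u <- length(union(expressed, measured))
  if (u == 0L) abort("both gene sets are empty")
  length(intersect(expressed, measured)) / u
}

#' Per-sample proteome coverage for a dataset
#'
#' For each sample, the Jaccard index between genes with a finite mRNA value
#' and genes with a finite protein value.
#'
#' @param mrna,protein Genes x samples matrices sharing sample ids.
#' @return Tibble with `sample_id`, `jaccard`, `n_expressed`, `n_measured`.
#' @export
proteome_coverage <- function(mrna, protein) {
  al <- align_matrices(mrna, protein)
  genes <- rownames(al[[1]])
  out <- lapply(colnames(al[[1]]), function(s) {
    e <- genes[is.finite(al[[1]][, s])]
    m <- genes[is.finite(al[[2]][, s])]
    tibble(sample_id = s, jaccard = coverage_jaccard(e, m),
           n_expressed = length(e), n_measured = length(m))
  })
  bind_rows(out)
}

# Build the OLS design from a covariate table: intercept + one-hot categorical
# covariates (treatment coding) + continuous columns. Single-level categorical
# covariates are dropped with a warning.
build_design <- function(cov, samples) {
  if (!"sample_id" %in% names(cov)) abort("covariate table needs `sample_id`")
  missing_s <- setdiff(samples, cov$sample_id)
  if (length(missing_s)) {
    abort(sprintf("samples absent from covariate table: %s",
                  paste(head(missing_s, 5), collapse = ", ")))
  }
  cov <- cov[match(samples, cov$sample_id), , drop = FALSE]
  vars <- setdiff(names(cov), "sample_id")
  keep <- character(0)
  for (v in vars) {
    if (is.numeric(cov[[v]])) {
      keep <- c(keep, v)
    } else if (length(unique(cov[[v]])) > 1L) {
      keep <- c(keep, v)
    } else {
      warn(sprintf("covariate `%s` has a single level; dropped from the design", v))
    }
  }
  if (!length(keep)) {
    return(matrix(1, length(samples), 1, dimnames = list(samples, "(Intercept)")))
  }
  df <- as.data.frame(lapply(cov[keep], function(x) {
    if (is.character(x)) factor(x) else x
  }))
  mm <- model.matrix(~ ., data = df)
  rownames(mm) <- samples
  mm
}

#' Regress confounders out of an omics matrix
#'
#' Per gene, ordinary least squares of the measurements on one-hot-coded
#' categorical covariates plus continuous covariates, with intercept. The
#' corrected value is the residual plus the fitted intercept, so the gene
#' stays on its original abundance scale. Missing entries are excluded from
#' the fit and stay missing. Genes with fewer complete observations than
#' design columns + 2 are left uncorrected (counted in a warning).
#'
#' @param m Genes x samples matrix.
#' @param covariates Tibble with `sample_id` plus covariate columns
#'   (numeric = continuous, character/factor = categorical).
#' @return Corrected matrix, same shape and dimnames as `m`.
#' @export
regress_out_covariates <- function(m, covariates) {
  check_omics_matrix(m)
  design <- build_design(covariates, colnames(m))
  p <- ncol(design)
  out <- m
  n_skipped <- 0L
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    ok <- is.finite(y)
    if (sum(ok) < p + 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    fit <- lm.fit(design[ok, , drop = FALSE], y[ok])
    out[i, ok] <- fit$residuals + fit$coefficients[1L]
  }
  if (n_skipped > 0L) {
    warn(sprintf("%d gene(s) left uncorrected (fewer complete observations than design columns + 2)",
                 n_skipped))
  }
  out
}

#' Mode of a Gaussian kernel density estimate
#'
#' Silverman's rule-of-thumb bandwidth (`bw.nrd0`); the mode is the grid
#' argmax of the density. Constant input returns the constant.
#'
#' @param x Numeric vector; non-finite values ignored.
#' @param n_grid Density grid size.
#' @return The estimated mode.
#' @export
kde_mode <- function(x, n_grid = 2048) {
  x <- x[is.finite(x)]
  if (!length(x)) abort("no finite values")
  if (length(unique(x)) == 1L) return(x[1])
  d <- density(x, bw = "nrd0", n = n_grid)
  d$x[which.max(d$y)]
}

#' Center each gene at its KDE mode
#'
#' Subtracts the mode of a Gaussian kernel density estimate of each gene's
#' values, so the bulk of the distribution sits at zero (robust to skew and
#' secondary modes, unlike mean-centering).
#'
#' @param m Genes x samples matrix; each gene needs at least 5 finite values.
#' @return Centered matrix.
#' @export
kde_center <- function(m) {
  check_omics_matrix(m)
  n_ok <- rowSums(is.finite(m))
  if (any(n_ok < 5L)) {
    abort(sprintf("%d gene(s) have fewer than 5 finite values", sum(n_ok < 5L)))
  }
  modes <- apply(m, 1L, kde_mode)
  m - modes
}

#' Keep genes measured in at least a fraction of samples
#'
#' @param m Genes x samples matrix.
#' @param min_fraction Minimum non-missing fraction (default 0.5, the usual
#'   "measured in at least half the samples" rule).
#' @return Filtered matrix, sample order unchanged.
#' @export
presence_filter <- function(m, min_fraction = 0.5) {
  check_omics_matrix(m)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  keep <- rowMeans(is.finite(m)) >= min_fraction
  if (!any(keep)) abort("presence filter removed every gene")
  m[keep, , drop = FALSE]
}
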