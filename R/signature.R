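# Attenuation-potential expression signature: per-gene correlation with the
# per-sample attenuation potential, signature scoring of new expression
# profiles, cross-validated logistic benchmarking, and per-drug response
# association.

#' Build the attenuation-potential expression signature
#'
#' Correlates each gene's expression with the per-sample attenuation
#' potential across samples (pairwise-complete Pearson). Constant genes get
#' missing entries.
#'
#' @param mrna Genes x samples expression matrix.
#' @param potential Named numeric vector, sample id -> attenuation potential
#'   (e.g. the `score` column of [sample_attenuation_potential()]).
#' @param min_obs Minimum samples with both values (default 20, also the
#'   floor for the whole analysis).
#' @return Tibble of class `attenuation_signature`: `gene`, `r`, `n`.
#' @export
build_signature <- function(mrna, potential, min_obs = 20L) {
  check_omics_matrix(mrna)
  if (is.null(names(potential))) abort("`potential` must be named by sample id")
  shared <- intersect(colnames(mrna), names(potential))
  if (length(shared) < 20L) abort("need at least 20 samples with both values")
  m <- mrna[, shared, drop = FALSE]
  p <- potential[shared]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    pr <- pearson_pairwise(m[i, ], p, min_obs)
    tibble(gene = rownames(m)[i], r = pr$r, n = pr$n)
  })
  out <- bind_rows(rows)
  class(out) <- c("attenuation_signature", class(out))
  out
}

#' Score samples against the attenuation signature
#'
#' Predicted attenuation potential of a sample = Pearson correlation, across
#' the genes shared between signature and expression matrix, between the
#' sample's expression profile and the signature's per-gene correlations.
#' Invariant to per-sample affine rescaling of expression.
#'
#' @param signature An `attenuation_signature` (or tibble `gene`, `r`).
#' @param expression Genes x samples matrix to score.
#' @param min_shared Minimum shared genes (default 50); fewer is an error
#'   reporting the overlap.
#' @return Tibble `sample_id`, `score`, `n_genes`.
#' @export
score_samples <- function(signature, expression, min_shared = 50L) {
  check_omics_matrix(expression, "expression")
  sig <- filter(as_tibble(signature), is.finite(.data$r))
  shared <- intersect(sig$gene, rownames(expression))
  if (length(shared) < min_shared) {
    abort(sprintf("only %d genes shared between signature and expression (< %d)",
                  length(shared), min_shared))
  }
  w <- sig$r[match(shared, sig$gene)]
  e <- expression[shared, , drop = FALSE]
  rows <- lapply(seq_len(ncol(e)), function(j) {
    pr <- pearson_pairwise(e[, j], w, 3L)
    tibble(sample_id = colnames(e)[j], score = pr$r, n_genes = pr$n)
  })
  bind_rows(rows)
}

# Vectorized one-way ANOVA F (2 groups) per gene on a genes x samples matrix.
anova_f_by_gene <- function(m, labels) {
  g <- as.integer(factor(labels))
  n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  m1 <- rowMeans(m[, g == 1L, drop = FALSE])
  m2 <- rowMeans(m[, g == 2L, drop = FALSE])
  ss1 <- rowSums((m[, g == 1L, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, g == 2L, drop = FALSE] - m2)^2)
  n <- n1 + n2
  grand <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- ss1 + ss2
  f <- (ssb / 1) / (ssw / (n - 2))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  list(f = f, p = p)
}

#' Cross-validated benchmark of the attenuation signature
#'
#' Repeatedly splits the cohort into stratified train/test groups. Per split:
#' per-gene ANOVA F between the two label groups on the training samples, BH
#' FDR, keep features with FDR below `feature_fdr`; fit an L2-regularised
#' logistic model on the kept features (regularisation strength picked from
#' `lambda_grid` by stratified 5-fold cross-validation on the training set);
#' report the held-out AROC. Splits with no surviving features fall back to
#' an intercept-only model (AROC 0.5) and are counted.
#'
#' @param expression Genes x samples matrix (no missing values).
#' @param labels Two-level factor/character per sample (e.g. strong/weak
#'   attenuation); both classes need at least 10 samples.
#' @param n_splits Number of random splits (default 1000).
#' @param test_fraction Held-out fraction per split (default 0.3).
#' @param feature_fdr FDR threshold for feature selection (default 0.05).
#' @param lambda_grid Ridge penalty grid for glmnet.
#' @param seed Integer seed; fixes the whole split sequence.
#' @return List of class `signature_benchmark`: `aroc` (per-split vector),
#'   `mean_aroc`, `sd_aroc`, `n_empty_feature_splits`, `n_splits`.
#' @export
benchmark_signature <- function(expression, labels, n_splits = 1000L,
                                test_fraction = 0.3, feature_fdr = 0.05,
                                lambda_grid = c(10, 1, 0.1, 0.01),
                                seed = 1L) {
  check_omics_matrix(expression, "expression")
  if (anyNA(expression)) abort("`expression` must be complete for benchmarking")
  labels <- factor(labels)
  if (nlevels(labels) != 2L) abort("`labels` must have exactly 2 levels")
  if (any(table(labels) < 10L)) abort("both classes need at least 10 samples")
  ns <- ncol(expression)
  stopifnot(length(labels) == ns)
  y <- as.integer(labels) - 1L
  x_all <- t(expression)

  withr::local_seed(seed)
  n_empty <- 0L
  arocs <- numeric(n_splits)
  for (b in seq_len(n_splits)) {
    test_idx <- unlist(lapply(split(seq_len(ns), labels), function(idx) {
      sample(idx, max(1L, round(test_fraction * length(idx))))
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(ns), test_idx)
    av <- anova_f_by_gene(expression[, train_idx, drop = FALSE], labels[train_idx])
    keep <- which(p.adjust(av$p, method = "BH") < feature_fdr)
    if (length(keep) == 0L) {
      n_empty <- n_empty + 1L
      arocs[b] <- 0.5
      next
    }
    xtr <- x_all[train_idx, keep, drop = FALSE]
    ytr <- y[train_idx]
    if (length(keep) == 1L) xtr <- cbind(xtr, 0)  # glmnet needs >= 2 columns
    # stratified 5-fold ids on the training samples
    foldid <- integer(length(ytr))
    for (cl in 0:1) {
      idx <- which(ytr == cl)
      foldid[idx] <- sample(rep_len(1:5, length(idx)))
    }
    cvfit <- glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = 0,
                               lambda = sort(lambda_grid, decreasing = TRUE),
                               foldid = foldid, type.measure = "deviance")
    xte <- x_all[test_idx, keep, drop = FALSE]
    if (length(keep) == 1L) xte <- cbind(xte, 0)
    pred <- as.numeric(predict(cvfit, newx = xte, s = "lambda.min"))
    arocs[b] <- aroc(pred, y[test_idx] == 1L)
  }
  if (n_empty > 0L) {
    inform(sprintf("%d split(s) with no surviving features (AROC 0.5 fallback)", n_empty))
  }
  structure(list(aroc = arocs, mean_aroc = mean(arocs), sd_aroc = sd(arocs),
                 n_empty_feature_splits = n_empty, n_splits = n_splits,
                 seed = seed),
            class = "signature_benchmark")
}

#' @export
print.signature_benchmark <- function(x, ...) {
  cat(sprintf("<signature_benchmark> %d splits: mean AROC %.3f (sd %.3f)\n",
              x$n_splits, x$mean_aroc, x$sd_aroc))
  invisible(x)
}

#' @export
tidy.signature_benchmark <- function(x, ...) {
  tibble(split = seq_along(x$aroc), aroc = x$aroc)
}

#' @export
glance.signature_benchmark <- function(x, ...) {
  tibble(mean_aroc = x$mean_aroc, sd_aroc = x$sd_aroc,
         n_splits = x$n_splits, n_empty_feature_splits = x$n_empty_feature_splits,
         seed = x$seed)
}

#' Associate predicted attenuation potential with drug response
#'
#' Per drug, OLS of the response (area under the dose-response curve; higher
#' = more resistant) on the predicted attenuation potential across cell
#' lines, with two-sided p-values and BH FDR across drugs. A positive slope
#' reads as "higher attenuation potential, more resistant". Drugs with fewer
#' than `min_n` complete cell lines are skipped and counted.
#'
#' @param predicted_potential Named numeric vector, cell line -> score.
#' @param drug_auc Drugs x cell-lines numeric matrix (missing allowed).
#' @param min_n Minimum complete cell lines per drug (default 20).
#' @return Tibble `drug`, `slope`, `r`, `p_value`, `fdr`, `n`.
#' @export
drug_associations <- function(predicted_potential, drug_auc, min_n = 20L) {
  if (is.null(names(predicted_potential))) abort("`predicted_potential` must be named")
  if (is.null(rownames(drug_auc)) || is.null(colnames(drug_auc))) {
    abort("`drug_auc` needs drug rownames and cell-line colnames")
  }
  shared <- intersect(colnames(drug_auc), names(predicted_potential))
  pot <- predicted_potential[shared]
  n_skipped <- 0L
  rows <- lapply(rownames(drug_auc), function(d) {
    yv <- drug_auc[d, shared]
    ok <- is.finite(yv) & is.finite(pot)
    n <- sum(ok)
    if (n < min_n || sd(pot[ok]) == 0 || sd(yv[ok]) == 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    fit <- lm.fit(cbind(1, pot[ok]), yv[ok])
    r <- cor(pot[ok], yv[ok])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    tibble(drug = d, slope = unname(fit$coefficients[2L]), r = r,
           p_value = p, n = n)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) abort("no drug with enough complete cell lines")
  if (n_skipped > 0L) inform(sprintf("%d drug(s) skipped (< %d complete cell lines)",
                                     n_skipped, min_n))
  out |> mutate(fdr = p.adjust(.data$p_value, method = "BH")) |>
    select("drug", "slope", "r", "p_value", "fdr", "n")
}
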