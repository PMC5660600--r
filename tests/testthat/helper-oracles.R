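# Independent brute-force oracles used to check the package's statistics.
# These deliberately re-derive each quantity from first principles and stay
# independent of the implementation paths they verify.

# Textbook Pearson correlation (sum formulas).
oracle_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Spearman rho via the rank-difference formula (tie-free inputs only).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# OLS coefficients from the normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Benjamini-Hochberg step-up, implemented literally: find the largest k with
# p_(k) <= k/m * q by scanning, then adjusted p by the cumulative-minimum
# definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cur_min <- 1
  for (i in m:1) {
    cur_min <- min(cur_min, p[o[i]] * m / i)
    adj[o[i]] <- cur_min
  }
  pmin(adj, 1)
}

# ROC AUC by explicit trapezoidal integration over all thresholds.
oracle_auc_trapezoid <- function(score, is_pos) {
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(score[is_pos] >= t), 0)
  fpr <- vapply(th, function(t) mean(score[!is_pos] >= t), 0)
  x <- c(0, fpr, 1); y <- c(0, tpr, 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# GSEA enrichment score by materialising the full running sum over every
# position of the ranked list (weight exponent 1).
oracle_gsea_es <- function(ranked, set_genes) {
  hit <- names(ranked) %in% set_genes
  w <- abs(ranked)
  W <- sum(w[hit])
  inc <- if (W > 0) ifelse(hit, w / W, 0) else ifelse(hit, 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, 1 / (length(ranked) - sum(hit)))
  walk <- cumsum(inc - dec)
  walk[which.max(abs(walk))]
}

# KDE mode by dense-grid argmax with Silverman bandwidth, independent of
# stats::density()'s FFT path.
oracle_kde_mode <- function(x, n_grid = 4096) {
  bw <- stats::bw.nrd0(x)
  g <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = n_grid)
  dens <- vapply(g, function(gi) mean(stats::dnorm(gi, x, bw)), 0)
  g[which.max(dens)]
}

# Complex membership table from a synthetic dataset's ground truth.
truth_membership <- function(ds) {
  tg <- ds$truth$gene[!is.na(ds$truth$gene$complex), ]
  tibble::tibble(complex_id = sprintf("cx%03d", tg$complex), gene_id = tg$gene)
}

# A small config with covariate effects and missingness switched off.
clean_config <- function(...) {
  simulation_config(
    covariate_effects = list(age = 0, gender = 0, tumour_type = 0, technology = 0),
    missing_rate = 0, ...
  )
}
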