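# GSEA-style enrichment of attenuation scores: weighted Kolmogorov-Smirnov
# running-sum enrichment score with a gene-set-membership permutation null.

#' Center a score vector at its KDE mode for enrichment ranking
#'
#' Subtracts the mode of a Gaussian KDE (Silverman bandwidth) so the ranking
#' metric is centered at zero before enrichment analysis. Constant input
#' maps to the zero vector.
#'
#' @param scores Numeric vector with at least 20 finite values.
#' @return Centered vector (names preserved).
#' @export
normalize_scores_for_ranking <- function(scores) {
  if (sum(is.finite(scores)) < 20L) abort("need at least 20 finite scores")
  scores - kde_mode(scores)
}

# Enrichment score for a set given hit positions in a ranked list.
# `weights_all` are the ranking scores in ranked (descending) order; hit
# increments are proportional to |score|^1, miss decrements uniform.
gsea_es <- function(hit_pos, weights_all, N) {
  k <- length(hit_pos)
  hp <- sort(hit_pos)
  w <- abs(weights_all[hp])
  W <- sum(w)
  if (W <= 0) {
    w <- rep(1, k)
    W <- k
  }
  cum_hit <- cumsum(w) / W
  miss_at <- (hp - seq_len(k)) / (N - k)
  up <- cum_hit - miss_at                 # running sum just after each hit
  down <- c(0, cum_hit[-k]) - miss_at     # just before each hit
  es_max <- max(up)
  es_min <- min(c(down, 0))
  if (es_max >= -es_min) es_max else es_min
}

#' Gene-set enrichment of a ranked score vector
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment: genes are
#' ranked by score (descending, ties broken by gene id for determinism); hit
#' increments are proportional to `|score|` (weight exponent 1) and miss
#' decrements are uniform. The null is built per set by `n_perm` random
#' permutations of set membership (random same-size gene sets); the two-sided
#' empirical p-value compares `|ES|` against the null with +1 smoothing, so
#' p is never 0 and never below `1/(n_perm + 1)`. FDR is Benjamini-Hochberg
#' across the reported sets.
#'
#' @param scores Named numeric vector, gene -> ranking score.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of membership permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param min_size Minimum set size after intersection with the scored genes;
#'   smaller or non-overlapping sets are skipped with a message.
#' @return Tibble of class `enrichment_table`: `set`, `es`, `p_value`, `fdr`,
#'   `size`.
#' @export
gsea <- function(scores, sets, n_perm = 1000L, seed = 1L, min_size = 5L) {
  if (is.null(names(scores))) abort("`scores` must be a named gene -> score vector")
  scores <- scores[is.finite(scores)]
  # descending score; ties broken by gene id
  ord <- order(-scores, names(scores), method = "radix")
  ranked <- scores[ord]
  genes <- names(ranked)
  N <- length(genes)
  pos_of <- setNames(seq_len(N), genes)

  sizes <- vapply(sets, function(s) sum(s %in% genes), 0L)
  usable <- sizes >= min_size & sizes < N
  if (!any(usable)) abort(sprintf("no set with >= %d members among scored genes", min_size))
  if (any(!usable)) {
    inform(sprintf("%d set(s) skipped (overlap < %d or not proper subsets)",
                   sum(!usable), min_size))
  }

  withr::local_seed(seed)
  rows <- lapply(names(sets)[usable], function(nm) {
    hits <- pos_of[intersect(sets[[nm]], genes)]
    es <- gsea_es(hits, ranked, N)
    k <- length(hits)
    null_es <- vapply(seq_len(n_perm), function(b) {
      gsea_es(sample.int(N, k), ranked, N)
    }, 0)
    p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    tibble(set = nm, es = es, p_value = p, size = k)
  })
  out <- bind_rows(rows) |>
    mutate(fdr = p.adjust(.data$p_value, method = "BH")) |>
    select("set", "es", "p_value", "fdr", "size")
  class(out) <- c("enrichment_table", class(out))
  out
}
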