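# Co-regulation analysis: all-pairs abundance correlation at one molecular
# level, interaction catalogs (complex / functional / signaling / metabolic
# positives) and ROC evaluation with randomized negative sets.

#' All unique pairwise gene-gene correlations at one molecular level
#'
#' Pairwise-complete Pearson correlation for every unordered gene pair;
#' exactly `choose(n_genes, 2)` rows. Pairs with fewer than `min_obs`
#' complete observations get `NA` correlations (flagged, not dropped).
#'
#' @param m Genes x samples matrix (at least 2 genes).
#' @param min_obs Minimum complete observations per pair (default 15).
#' @return Tibble `gene_a`, `gene_b` (`gene_a < gene_b`), `r`, `n`.
#' @export
pairwise_correlations <- function(m, min_obs = 15L) {
  check_omics_matrix(m)
  if (nrow(m) < 2L) abort("need at least 2 genes")
  x <- t(m)
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  ok <- !is.na(x)
  nobs <- crossprod(ok)          # complete pairs per gene pair
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- tibble(
    gene_a = rownames(m)[idx[, 1]],
    gene_b = rownames(m)[idx[, 2]],
    r = r[idx],
    n = as.integer(nobs[idx])
  )
  out$r[out$n < min_obs] <- NA_real_
  out
}

#' Assemble positive interaction-pair sets from catalogs
#'
#' Positives per source: `complexes` — all unordered co-members of at least
#' one complex (deduplicated across complexes); `functional` — scored edges
#' with score at or above `functional_score_min` (STRING-like, default 900 =
#' highest confidence); `signaling` — kinase/phosphatase-substrate edges as
#' given; `metabolic` — co-membership within any pathway gene set. All pairs
#' are restricted to the measured gene `universe`; self-edges are dropped
#' with a count.
#'
#' @param complexes Tibble `complex_id`, `gene_id` (long membership format).
#' @param functional_edges Optional tibble `gene_a`, `gene_b`, `score`.
#' @param signaling_edges Optional tibble `gene_a`, `gene_b`.
#' @param pathways Optional named list of gene sets (GMT semantics).
#' @param universe Character vector of measured genes.
#' @param functional_score_min Score threshold for functional edges.
#' @return Named list of class `interaction_sets`; each element a tibble
#'   `gene_a`, `gene_b` with `gene_a < gene_b`.
#' @export
build_interaction_sets <- function(complexes = NULL, functional_edges = NULL,
                                   signaling_edges = NULL, pathways = NULL,
                                   universe, functional_score_min = 900) {
  if (!length(universe)) abort("`universe` must be non-empty")
  universe <- unique(universe)

  comember_pairs <- function(groups) {
    # groups: list of gene vectors; returns deduplicated unordered pairs
    pieces <- lapply(groups, function(g) {
      g <- sort(unique(intersect(g, universe)))
      if (length(g) < 2L) return(NULL)
      idx <- utils::combn(length(g), 2L)
      tibble(gene_a = g[idx[1, ]], gene_b = g[idx[2, ]])
    })
    out <- bind_rows(pieces)
    if (!nrow(out)) return(tibble(gene_a = character(0), gene_b = character(0)))
    distinct(out)
  }

  canon_edges <- function(edges) {
    edges <- filter(edges, .data$gene_a %in% universe, .data$gene_b %in% universe)
    n_self <- sum(edges$gene_a == edges$gene_b)
    if (n_self > 0L) inform(sprintf("%d self-edge(s) dropped", n_self))
    edges <- filter(edges, .data$gene_a != .data$gene_b)
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    distinct(edges, .data$gene_a, .data$gene_b)
  }

  out <- list()
  if (!is.null(complexes)) {
    out$complexes <- comember_pairs(split(complexes$gene_id, complexes$complex_id))
  }
  if (!is.null(functional_edges)) {
    keep <- filter(functional_edges, .data$score >= functional_score_min)
    out$functional <- canon_edges(keep)
  }
  if (!is.null(signaling_edges)) {
    out$signaling <- canon_edges(signaling_edges)
  }
  if (!is.null(pathways)) {
    out$metabolic <- comember_pairs(pathways)
  }
  if (!length(out)) abort("no interaction source supplied")
  structure(out, class = c("interaction_sets", "list"))
}

#' AROC of pairwise correlations against a positive interaction set
#'
#' Uses the correlation coefficient (not its absolute value) as the
#' classifier score. Because non-interacting pairs vastly outnumber
#' interacting ones, each of `n_negative_draws` draws samples a negative set
#' of the same size as the positives from the non-positive pairs (without
#' replacement within a draw) and computes the AROC by the rank-sum identity;
#' the mean and SD across draws are reported.
#'
#' @param pairs Tibble from [pairwise_correlations()].
#' @param positives Tibble `gene_a`, `gene_b` of positive pairs.
#' @param n_negative_draws Number of randomized negative sets (default 5).
#' @param seed Integer seed.
#' @return One-row tibble: `mean_aroc`, `sd_aroc`, `n_positive`,
#'   `n_negative`, `n_draws`.
#' @export
interaction_aroc <- function(pairs, positives, n_negative_draws = 5L, seed = 1L) {
  pairs <- filter(pairs, is.finite(.data$r))
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  pos_key <- unique(pair_key(positives$gene_a, positives$gene_b))
  is_pos <- key %in% pos_key
  n_pos <- sum(is_pos)
  if (n_pos < 10L) abort("need at least 10 positive pairs with finite correlations")
  neg_pool <- which(!is_pos)
  if (length(neg_pool) < n_pos) abort("insufficient non-positive pairs to sample negatives")
  r_pos <- pairs$r[is_pos]
  withr::local_seed(seed)
  arocs <- vapply(seq_len(n_negative_draws), function(b) {
    neg <- sample(neg_pool, n_pos)
    aroc(c(r_pos, pairs$r[neg]), rep(c(TRUE, FALSE), each = n_pos))
  }, 0)
  tibble(mean_aroc = mean(arocs), sd_aroc = sd(arocs),
         n_positive = n_pos, n_negative = n_pos, n_draws = n_negative_draws)
}
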