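# Attenuation analysis: CNV-mRNA and CNV-protein Pearson correlations per
# gene (or per sample), the attenuation score (their difference), and
# two-component Gaussian-mixture classification of the scores.

#' Per-gene CNV-mRNA and CNV-protein correlations and attenuation scores
#'
#' For every gene present at all three levels, the Pearson correlation over
#' pairwise-complete samples between CNV and mRNA and between CNV and
#' protein. The attenuation score is `r(CNV, mRNA) - r(CNV, protein)`:
#' positive values indicate post-transcriptional buffering of dosage changes.
#' Genes with fewer than `min_obs` complete pairs for either correlation, or
#' with zero CNV variance, get missing correlations (counted in a message)
#' and are excluded from downstream scoring.
#'
#' @param cnv,mrna,protein Genes x samples matrices; genes and samples are
#'   intersected across the three levels.
#' @param min_obs Minimum complete pairs per correlation (default 15).
#' @return A tibble of class `attenuation_table` with columns `entity`,
#'   `r_cnv_mrna`, `r_cnv_protein`, `n_obs_mrna`, `n_obs_protein`, `score`.
#' @seealso [classify_attenuation()], [gene_attenuation()]
#' @export
feature_correlations <- function(cnv, mrna, protein, min_obs = 15L) {
  al <- align_matrices(cnv, mrna, protein)
  cnv <- al[[1]]; mrna <- al[[2]]; protein <- al[[3]]
  n_flat <- 0L
  res <- lapply(seq_len(nrow(cnv)), function(i) {
    rm_ <- pearson_pairwise(cnv[i, ], mrna[i, ], min_obs)
    rp_ <- pearson_pairwise(cnv[i, ], protein[i, ], min_obs)
    tibble(entity = rownames(cnv)[i],
           r_cnv_mrna = rm_$r, r_cnv_protein = rp_$r,
           n_obs_mrna = rm_$n, n_obs_protein = rp_$n)
  })
  out <- bind_rows(res) |>
    mutate(score = .data$r_cnv_mrna - .data$r_cnv_protein)
  n_flat <- sum(is.na(out$r_cnv_mrna) | is.na(out$r_cnv_protein))
  if (n_flat > 0L) {
    inform(sprintf("%d gene(s) with missing correlations (zero CNV variance or < %d complete pairs)",
                   n_flat, min_obs))
  }
  class(out) <- c("attenuation_table", class(out))
  out
}

#' Classify attenuation scores with a two-component Gaussian mixture
#'
#' Fits a univariate two-component Gaussian mixture (unequal variances) to
#' the finite scores; the component with the larger mean is labelled
#' `attenuated`. A point is assigned to `attenuated` only when its posterior
#' exceeds 0.5 (ties go to `background`). The stringent flag additionally
#' requires `|score| > 0.3`. Near-constant scores trigger a single-cluster
#' fallback: every label `background`, with a warning.
#'
#' @param scores Numeric vector (at least 20 finite values).
#' @param seed Seed recorded in the fit report; the fit itself is
#'   deterministic (model-based hierarchical initialisation).
#' @return A list with `labels` (factor `attenuated`/`background` aligned to
#'   `scores`, `NA` for non-finite input), `posterior` (P(attenuated)),
#'   `stringent` (logical) and `fit` (class `gmm_fit`: means, variances,
#'   weights, loglik, converged).
#' @export
classify_attenuation <- function(scores, seed = 1L) {
  finite <- is.finite(scores)
  if (sum(finite) < 20L) abort("need at least 20 finite scores")
  x <- scores[finite]
  labels <- factor(rep(NA_character_, length(scores)),
                   levels = c("attenuated", "background"))
  posterior <- rep(NA_real_, length(scores))

  if (sd(x) < 1e-8) {
    warn("near-constant scores: single-cluster fallback, all labels background")
    labels[finite] <- "background"
    posterior[finite] <- 0
    fit <- structure(list(means = mean(x), variances = 0, weights = 1,
                          loglik = NA_real_, n = length(x), seed = seed,
                          converged = FALSE, fallback = TRUE),
                     class = "gmm_fit")
    return(list(labels = labels, posterior = posterior,
                stringent = !is.na(labels) & labels == "attenuated" & abs(scores) > 0.3,
                fit = fit))
  }

  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(mc)) {
    # unequal variances can degenerate on point-mass clusters; retry pooled
    mc <- mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  }
  if (is.null(mc)) {
    warn("mixture fit failed: single-cluster fallback, all labels background")
    labels[finite] <- "background"
    posterior[finite] <- 0
    fit <- structure(list(means = mean(x), variances = var(x), weights = 1,
                          loglik = NA_real_, n = length(x), seed = seed,
                          converged = FALSE, fallback = TRUE),
                     class = "gmm_fit")
  } else {
    att_comp <- which.max(mc$parameters$mean)
    post_att <- mc$z[, att_comp]
    labels[finite] <- ifelse(post_att > 0.5, "attenuated", "background")
    posterior[finite] <- post_att
    fit <- structure(list(
      means = unname(mc$parameters$mean),
      variances = unname(mc$parameters$variance$sigmasq),
      weights = unname(mc$parameters$pro),
      attenuated_component = att_comp,
      loglik = mc$loglik, n = length(x), seed = seed,
      converged = TRUE, fallback = FALSE
    ), class = "gmm_fit")
  }
  list(labels = labels, posterior = posterior,
       stringent = !is.na(labels) & labels == "attenuated" & abs(scores) > 0.3,
       fit = fit)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit>", length(x$means), "component(s) on", x$n, "scores\n")
  cat("  means:", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble(component = seq_along(x$means),
         mean = x$means,
         variance = x$variances,
         weight = x$weights,
         attenuated = seq_along(x$means) == (x$attenuated_component %||% NA_integer_))
}

#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(n = x$n, loglik = x$loglik, converged = x$converged,
         fallback = x$fallback, seed = x$seed)
}

# Shared: attach GMM classification columns to a correlation table.
classify_table <- function(tab, seed) {
  cls <- classify_attenuation(tab$score, seed = seed)
  out <- tab |>
    mutate(gmm_class = cls$labels,
           gmm_posterior = cls$posterior,
           stringent_flag = cls$stringent)
  attr(out, "gmm_fit") <- cls$fit
  class(out) <- unique(c("attenuation_table", class(out)))
  out
}

#' Per-gene attenuation analysis (correlations + mixture classification)
#'
#' Convenience wrapper: [feature_correlations()] followed by
#' [classify_attenuation()] on the scores. The fitted mixture is attached as
#' attribute `"gmm_fit"`.
#'
#' @inheritParams feature_correlations
#' @param seed Seed recorded in the mixture fit report.
#' @return An `attenuation_table` tibble with added `gmm_class`,
#'   `gmm_posterior`, `stringent_flag` columns.
#' @export
gene_attenuation <- function(cnv, mrna, protein, min_obs = 15L, seed = 1L) {
  tab <- feature_correlations(cnv, mrna, protein, min_obs = min_obs)
  classify_table(tab, seed)
}

#' Per-sample attenuation potential
#'
#' The per-sample analogue of the per-gene analysis: for each sample, the
#' Pearson correlation across genes between CNV and mRNA and between CNV and
#' protein (pairwise-complete over the genes measured in that sample), the
#' attenuation-potential score `r(CNV, mRNA) - r(CNV, protein)`, and the same
#' two-component mixture classification. Samples in the higher-mean component
#' attenuate dosage changes proteome-wide.
#'
#' @inheritParams gene_attenuation
#' @return An `attenuation_table` tibble, one row per sample (`entity` =
#'   sample id), with the mixture fit attached as attribute `"gmm_fit"`.
#' @export
sample_attenuation_potential <- function(cnv, mrna, protein, min_obs = 15L,
                                         seed = 1L) {
  al <- align_matrices(cnv, mrna, protein)
  cnv <- al[[1]]; mrna <- al[[2]]; protein <- al[[3]]
  res <- lapply(seq_len(ncol(cnv)), function(j) {
    rm_ <- pearson_pairwise(cnv[, j], mrna[, j], min_obs)
    rp_ <- pearson_pairwise(cnv[, j], protein[, j], min_obs)
    tibble(entity = colnames(cnv)[j],
           r_cnv_mrna = rm_$r, r_cnv_protein = rp_$r,
           n_obs_mrna = rm_$n, n_obs_protein = rp_$n)
  })
  tab <- bind_rows(res) |>
    mutate(score = .data$r_cnv_mrna - .data$r_cnv_protein)
  classify_table(tab, seed)
}

#' Write an attenuation table as TSV
#'
#' Stable column names: entity, r_cnv_mrna, r_cnv_protein, n_obs_mrna,
#' n_obs_protein, score, class, posterior, stringent.
#'
#' @param tab An `attenuation_table`.
#' @param path Output file.
#' @export
write_attenuation <- function(tab, path) {
  out <- as_tibble(tab)
  if ("gmm_class" %in% names(out)) {
    out <- rename(out, class = "gmm_class", posterior = "gmm_posterior",
                  stringent = "stringent_flag")
  }
  readr::write_tsv(out, path)
  invisible(path)
}
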