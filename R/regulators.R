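# Rate-limiting-subunit discovery by two-stage residual regression. Stage
# one regresses a protein on its own transcript (P_y = beta * T_y + psi, with
# intercept); the residual P_y' carries the post-transcriptional variability.
# Stage two associates P_y' with the CNV (or transcript) of a complex
# co-member x (P_y' = beta2 * x + psi), scored by an F test and BH FDR.

#' Regress a protein on its own transcript
#'
#' Stage one of the two-stage model: OLS with intercept of the protein vector
#' on the transcript vector over complete pairs. The residual profile is the
#' post-transcriptional component of the protein's variability; samples
#' missing either value carry missing residuals. A constant transcript falls
#' back to an intercept-only fit (residual = centered protein), with a
#' warning.
#'
#' @param protein_y,transcript_y Numeric sample vectors of equal length.
#' @param min_obs Minimum complete pairs (default 10).
#' @return List of class `residual_profile`: `residuals` (aligned to input,
#'   `NA` where incomplete), `beta`, `intercept`, `n`.
#' @export
residualize <- function(protein_y, transcript_y, min_obs = 10L) {
  stopifnot(length(protein_y) == length(transcript_y))
  ok <- is.finite(protein_y) & is.finite(transcript_y)
  n <- sum(ok)
  if (n < min_obs) abort(sprintf("only %d complete pairs (< %d)", n, min_obs))
  p <- protein_y[ok]
  t_ <- transcript_y[ok]
  res <- rep(NA_real_, length(protein_y))
  if (sd(t_) == 0) {
    warn("constant transcript: intercept-only fit")
    beta <- 0
    intercept <- mean(p)
    res[ok] <- p - intercept
  } else {
    fit <- lm.fit(cbind(1, t_), p)
    beta <- fit$coefficients[2L]
    intercept <- fit$coefficients[1L]
    res[ok] <- fit$residuals
  }
  names(res) <- names(protein_y)
  structure(list(residuals = res, beta = unname(beta),
                 intercept = unname(intercept), n = n),
            class = "residual_profile")
}

#' Enumerate directed complex co-member pairs
#'
#' All ordered pairs (x -> y), x != y, that co-occur in at least one complex,
#' with y measured at both protein and transcript level (needed for the
#' residual) and x measured at the predictor level. Deduplicated across
#' complexes.
#'
#' @param complexes Tibble `complex_id`, `gene_id`.
#' @param y_genes Genes measured at protein and transcript level.
#' @param x_genes Genes measured at the predictor level.
#' @return Tibble `px`, `py`.
#' @export
enumerate_directed_pairs <- function(complexes, y_genes, x_genes) {
  if (!nrow(complexes)) abort("empty complex membership table")
  groups <- split(unique(complexes)$gene_id, unique(complexes)$complex_id)
  pieces <- lapply(groups, function(g) {
    g <- unique(g)
    if (length(g) < 2L) return(NULL)
    expand.grid(px = g, py = g, stringsAsFactors = FALSE)
  })
  out <- bind_rows(pieces) |>
    filter(.data$px != .data$py,
           .data$px %in% x_genes,
           .data$py %in% y_genes) |>
    distinct() |>
    as_tibble()
  arrange(out, .data$px, .data$py)
}

#' Test directed regulatory associations within complexes
#'
#' For each enumerated pair (x -> y): stage-one residuals `P_y'` from
#' [residualize()], then stage-two OLS of `P_y'` on the predictor of x (CNV
#' states treated as numeric, or the transcript of x), with intercept. The
#' predictor is scored with an F statistic against the intercept-only model
#' (df 1 and n - 2; for a single predictor F = t^2) and a two-sided p-value
#' from the F distribution. P-values are BH-adjusted jointly across all
#' tested pairs at this predictor level. Pairs with a zero-variance predictor
#' or fewer than `min_obs` complete observations are skipped and counted.
#'
#' @param protein,mrna,cnv Genes x samples matrices on shared samples.
#' @param pairs Tibble `px`, `py` from [enumerate_directed_pairs()].
#' @param predictor_level `"cnv"` or `"transcript"`.
#' @param fdr_threshold Significance threshold on the BH FDR (default 0.05).
#' @param min_obs Minimum complete observations per fit (default 10).
#' @return Tibble of class `regulatory_associations`: `px`, `py`,
#'   `predictor_level`, `beta`, `f_statistic`, `p_value`, `fdr`, `n`, `sign`,
#'   `significant`. Attribute `"n_skipped"` counts skipped pairs.
#' @export
test_regulatory_pairs <- function(protein, mrna, cnv = NULL, pairs,
                                  predictor_level = c("cnv", "transcript"),
                                  fdr_threshold = 0.05, min_obs = 10L) {
  predictor_level <- match.arg(predictor_level)
  if (predictor_level == "cnv" && is.null(cnv)) abort("`cnv` required for cnv-level testing")
  pred_m <- if (predictor_level == "cnv") cnv else mrna
  al <- align_matrices(protein, mrna)
  samples <- intersect(colnames(al[[1]]), colnames(pred_m))
  if (length(samples) < min_obs) abort("too few shared samples")
  protein <- al[[1]][, samples, drop = FALSE]
  mrna <- al[[2]][, samples, drop = FALSE]
  pred_m <- pred_m[, samples, drop = FALSE]

  pairs <- filter(pairs, .data$py %in% rownames(protein), .data$px %in% rownames(pred_m))
  resid_cache <- new.env(parent = emptyenv())
  get_resid <- function(y) {
    if (!exists(y, envir = resid_cache, inherits = FALSE)) {
      rp <- tryCatch(suppressWarnings(
        residualize(protein[y, ], mrna[y, ], min_obs = min_obs)),
        error = function(e) NULL)
      assign(y, if (is.null(rp)) NULL else rp$residuals, envir = resid_cache)
    }
    resid_cache[[y]]
  }

  n_skipped <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    py <- pairs$py[i]; px <- pairs$px[i]
    ry <- get_resid(py)
    if (is.null(ry)) { n_skipped <- n_skipped + 1L; next }
    x <- pred_m[px, ]
    ok <- is.finite(ry) & is.finite(x)
    n <- sum(ok)
    if (n < min_obs || sd(x[ok]) == 0) { n_skipped <- n_skipped + 1L; next }
    yv <- ry[ok]; xv <- x[ok]
    fit <- lm.fit(cbind(1, xv), yv)
    rss1 <- sum(fit$residuals^2)
    rss0 <- sum((yv - mean(yv))^2)
    f_stat <- (rss0 - rss1) / (rss1 / (n - 2))
    p <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
    rows[[i]] <- tibble(px = px, py = py, predictor_level = predictor_level,
                        beta = unname(fit$coefficients[2L]),
                        f_statistic = f_stat, p_value = p, n = n)
  }
  out <- bind_rows(rows)
  if (!nrow(out)) abort("no testable pairs")
  out <- out |>
    mutate(fdr = p.adjust(.data$p_value, method = "BH"),
           sign = ifelse(.data$beta >= 0, "positive", "negative"),
           significant = .data$fdr < fdr_threshold) |>
    select("px", "py", "predictor_level", "beta", "f_statistic", "p_value",
           "fdr", "n", "sign", "significant")
  if (n_skipped > 0L) {
    inform(sprintf("%d pair(s) skipped (zero-variance predictor or < %d observations)",
                   n_skipped, min_obs))
  }
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("regulatory_associations", class(out))
  out
}

#' Annotate CNV-level associations with transcript-level support
#'
#' Flags each CNV-level association that is also significant when the
#' predictor is the transcript of x (the dual-evidence highlight).
#'
#' @param cnv_assoc,transcript_assoc Outputs of [test_regulatory_pairs()] at
#'   the two predictor levels.
#' @return `cnv_assoc` with a logical `transcript_support` column.
#' @export
add_transcript_support <- function(cnv_assoc, transcript_assoc) {
  sig_t <- filter(transcript_assoc, .data$significant)
  key_t <- paste(sig_t$px, sig_t$py, sep = "\r")
  mutate(cnv_assoc,
         transcript_support = paste(.data$px, .data$py, sep = "\r") %in% key_t)
}

#' Compare predicted regulatory effects with knockdown measurements
#'
#' Spearman correlation between the stage-two association effect sizes and
#' experimentally measured partner abundance changes after knockdown of the
#' putative rate-limiting subunit, over the overlapping directed pairs.
#'
#' @param assoc A `regulatory_associations` tibble.
#' @param knockdown_effects Tibble `px`, `py`, `effect` (measured abundance
#'   change of y upon knockdown of x).
#' @return One-row tibble: `rho`, `p_value`, `n_overlap`.
#' @export
compare_to_knockdowns <- function(assoc, knockdown_effects) {
  m <- dplyr::inner_join(as_tibble(assoc), knockdown_effects,
                         by = c("px", "py"))
  if (nrow(m) < 5L) abort(sprintf("only %d overlapping pairs (< 5)", nrow(m)))
  ct <- suppressWarnings(cor.test(m$beta, m$effect, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n_overlap = nrow(m))
}
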