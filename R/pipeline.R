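# End-to-end driver: preprocess -> attenuation -> enrichment -> co-regulation
# -> regulators -> signature, with a single config object, explicit seeds and
# a run manifest. Rerunning with an identical config reproduces every output
# byte-identically.

#' Pipeline configuration
#'
#' @param simulate A [simulation_config()] to generate the inputs, or `NULL`
#'   to read them from files.
#' @param cnv,mrna,protein,covariates,complexes Input file paths (TSV; see
#'   [read_omics()], [read_covariates()], [read_complexes()]); ignored when
#'   `simulate` is given.
#' @param gene_sets Optional GMT path for enrichment; when absent, the
#'   complex memberships double as gene sets.
#' @param min_obs Minimum complete pairs for correlations.
#' @param presence_fraction Presence-filter threshold for the protein matrix.
#' @param n_perm GSEA permutations.
#' @param n_negative_draws Randomized negative sets for the co-regulation ROC.
#' @param fdr_threshold FDR threshold for regulatory associations.
#' @param n_benchmark_splits Splits for the signature benchmark (0 disables).
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, cnv = NULL, mrna = NULL,
                            protein = NULL, covariates = NULL,
                            complexes = NULL, gene_sets = NULL,
                            min_obs = 15L, presence_fraction = 0.5,
                            n_perm = 1000L, n_negative_draws = 5L,
                            fdr_threshold = 0.05, n_benchmark_splits = 100L,
                            seed = 1L, out_dir = tempfile("cnvbuffer_run_")) {
  stopifnot(presence_fraction > 0, presence_fraction <= 1,
            fdr_threshold > 0, fdr_threshold <= 1)
  cfg <- list(simulate = simulate, cnv = cnv, mrna = mrna, protein = protein,
              covariates = covariates, complexes = complexes,
              gene_sets = gene_sets, min_obs = as.integer(min_obs),
              presence_fraction = presence_fraction,
              n_perm = as.integer(n_perm),
              n_negative_draws = as.integer(n_negative_draws),
              fdr_threshold = fdr_threshold,
              n_benchmark_splits = as.integer(n_benchmark_splits),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

read_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    ds <- simulate_dataset(config$simulate)
    memb <- ds$truth$gene |>
      filter(!is.na(.data$complex)) |>
      mutate(complex_id = sprintf("cx%03d", .data$complex)) |>
      select(complex_id, gene_id = "gene")
    return(list(cnv = ds$cnv, mrna = ds$mrna, protein = ds$protein,
                covariates = ds$covariates, complexes = memb, truth = ds$truth))
  }
  for (f in c("cnv", "mrna", "protein", "covariates", "complexes")) {
    if (is.null(config[[f]])) abort(sprintf("pipeline input `%s` not configured", f))
    if (!file.exists(config[[f]])) abort(sprintf("input file not found: %s", config[[f]]))
  }
  list(cnv = read_omics(config$cnv), mrna = read_omics(config$mrna),
       protein = read_omics(config$protein),
       covariates = read_covariates(config$covariates),
       complexes = read_complexes(config$complexes), truth = NULL)
}

#' Run the full attenuation analysis
#'
#' Executes preprocess, per-gene attenuation, enrichment, co-regulation,
#' regulator discovery and the per-sample signature stages, writing result
#' TSVs and a JSON manifest (package version, seeds, counts at each filter
#' step) to `config$out_dir`. Identical config and seed reproduce all
#' outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- read_pipeline_inputs(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  counts <- list(genes_input = nrow(inp$protein), samples_input = ncol(inp$protein))

  # --- preprocess ---------------------------------------------------------
  coverage <- proteome_coverage(inp$mrna, inp$protein)
  readr::write_tsv(coverage, out("coverage.tsv"))
  protein <- presence_filter(inp$protein, config$presence_fraction)
  counts$genes_after_presence_filter <- nrow(protein)
  mrna <- suppressWarnings(regress_out_covariates(inp$mrna, inp$covariates))
  protein <- suppressWarnings(regress_out_covariates(protein, inp$covariates))
  mrna <- kde_center(mrna)
  protein <- kde_center(protein)

  # --- per-gene attenuation ----------------------------------------------
  att <- suppressMessages(gene_attenuation(inp$cnv, mrna, protein,
                                           min_obs = config$min_obs,
                                           seed = config$seed))
  write_attenuation(att, out("attenuation_gene.tsv"))
  scored <- filter(att, is.finite(.data$score))
  counts$genes_scored <- nrow(scored)
  counts$genes_attenuated <- sum(scored$gmm_class == "attenuated", na.rm = TRUE)
  counts$genes_attenuated_stringent <- sum(scored$stringent_flag, na.rm = TRUE)

  # --- enrichment ---------------------------------------------------------
  sets <- if (!is.null(config$gene_sets)) {
    read_gmt(config$gene_sets)
  } else {
    split(inp$complexes$gene_id, inp$complexes$complex_id)
  }
  scores <- setNames(scored$score, scored$entity)
  enr <- tryCatch(
    suppressMessages(gsea(normalize_scores_for_ranking(scores), sets,
                          n_perm = config$n_perm, seed = config$seed)),
    error = function(e) NULL)
  if (!is.null(enr)) {
    readr::write_tsv(enr, out("enrichment.tsv"))
    counts$gene_sets_tested <- nrow(enr)
  }

  # --- co-regulation ------------------------------------------------------
  universe <- intersect(rownames(protein), rownames(mrna))
  pc_protein <- pairwise_correlations(protein[universe, , drop = FALSE],
                                      min_obs = config$min_obs)
  pc_mrna <- pairwise_correlations(mrna[universe, , drop = FALSE],
                                   min_obs = config$min_obs)
  counts$pairwise_coefficients <- nrow(pc_protein) + nrow(pc_mrna)
  isets <- suppressMessages(build_interaction_sets(complexes = inp$complexes,
                                                   universe = universe))
  aroc_tab <- bind_rows(
    mutate(interaction_aroc(pc_protein, isets$complexes,
                            config$n_negative_draws, seed = config$seed),
           level = "protein"),
    mutate(interaction_aroc(pc_mrna, isets$complexes,
                            config$n_negative_draws, seed = config$seed),
           level = "transcript"))
  readr::write_tsv(aroc_tab, out("coregulation_aroc.tsv"))

  # --- regulators ---------------------------------------------------------
  pairs <- enumerate_directed_pairs(inp$complexes,
                                    y_genes = universe,
                                    x_genes = rownames(inp$cnv))
  counts$directed_pairs_cnv <- nrow(pairs)
  assoc_cnv <- suppressMessages(
    test_regulatory_pairs(protein, mrna, inp$cnv, pairs, "cnv",
                          fdr_threshold = config$fdr_threshold,
                          min_obs = config$min_obs))
  pairs_t <- enumerate_directed_pairs(inp$complexes,
                                      y_genes = universe,
                                      x_genes = rownames(mrna))
  assoc_t <- suppressMessages(
    test_regulatory_pairs(protein, mrna, NULL, pairs_t, "transcript",
                          fdr_threshold = config$fdr_threshold,
                          min_obs = config$min_obs))
  assoc_cnv <- add_transcript_support(assoc_cnv, assoc_t)
  readr::write_tsv(assoc_cnv, out("regulators_cnv.tsv"))
  readr::write_tsv(assoc_t, out("regulators_transcript.tsv"))
  counts$regulators_cnv_significant <- sum(assoc_cnv$significant)
  counts$regulators_transcript_significant <- sum(assoc_t$significant)

  # --- per-sample attenuation + signature ---------------------------------
  satt <- suppressMessages(sample_attenuation_potential(inp$cnv, mrna, protein,
                                                        min_obs = config$min_obs,
                                                        seed = config$seed))
  write_attenuation(satt, out("attenuation_sample.tsv"))
  counts$samples_high_attenuation <- sum(satt$gmm_class == "attenuated", na.rm = TRUE)
  potential <- setNames(satt$score, satt$entity)
  sig <- build_signature(mrna, potential)
  readr::write_tsv(sig, out("signature.tsv"))

  bench <- NULL
  if (config$n_benchmark_splits > 0L) {
    labels <- satt$gmm_class[match(colnames(mrna), satt$entity)]
    bench <- tryCatch(
      suppressMessages(benchmark_signature(mrna, labels,
                                           n_splits = config$n_benchmark_splits,
                                           seed = config$seed)),
      error = function(e) NULL)
    if (!is.null(bench)) {
      readr::write_tsv(glance(bench), out("signature_benchmark.tsv"))
      counts$benchmark_mean_aroc <- bench$mean_aroc
    }
  }

  manifest <- list(
    package = "cnvbuffer",
    version = as.character(utils::packageVersion("cnvbuffer")),
    seed = config$seed,
    parameters = config[c("min_obs", "presence_fraction", "n_perm",
                          "n_negative_draws", "fdr_threshold",
                          "n_benchmark_splits")],
    counts = counts
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
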