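# Generator: determinism, the noise-free dosage chain, ground-truth structure
# and config validation.

test_that("noise-free chain propagates CNV perfectly to both levels", {
  cfg <- clean_config(n_samples = 50, n_genes = 80, n_complexes = 5,
                      complex_size_range = c(4, 6),
                      attenuated_gamma_range = c(1, 1),
                      mrna_noise_sd = 0, protein_noise_sd = 0, seed = 2)
  ds <- simulate_dataset(cfg)
  for (i in seq_len(nrow(ds$cnv))) {
    if (sd(ds$cnv[i, ]) > 0) {
      expect_equal(cor(ds$cnv[i, ], ds$mrna[i, ]), 1, tolerance = 1e-12)
      expect_equal(cor(ds$cnv[i, ], ds$protein[i, ]), 1, tolerance = 1e-12)
    }
  }
})

test_that("equal configs and seeds give identical datasets", {
  cfg <- simulation_config(n_samples = 30, n_genes = 50, n_complexes = 4,
                           complex_size_range = c(4, 5), seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$cnv, d2$cnv)
  expect_identical(d1$mrna, d2$mrna)
  expect_identical(d1$protein, d2$protein)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$truth$gene, d2$truth$gene)
  d3 <- simulate_dataset(simulation_config(n_samples = 30, n_genes = 50,
                                           n_complexes = 4,
                                           complex_size_range = c(4, 5),
                                           seed = 100))
  expect_false(identical(d1$protein, d3$protein))
})

test_that("protein missingness tracks the configured rate", {
  ds <- simulate_dataset(simulation_config(n_samples = 200, n_genes = 500,
                                           missing_rate = 0.2, seed = 5))
  expect_lt(abs(mean(is.na(ds$protein)) - 0.2), 0.02)
  ds0 <- simulate_dataset(clean_config(n_samples = 30, n_genes = 40,
                                       n_complexes = 3, seed = 5))
  expect_false(anyNA(ds0$protein))
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(simulation_config(cnv_state_probs = c(0.5, 0.5, 0.2, 0, 0)),
               "cnv_state_probs")
  expect_error(simulation_config(attenuated_gamma_range = c(-0.1, 0.5)),
               "gamma")
  expect_error(simulation_config(missing_rate = 1.2), "missing_rate")
  expect_error(simulation_config(n_genes = 20, complexes = list(
    list(genes = 1:5, gamma = c(0.5, 0.5, 0.5, 0.5, 1.4)))), "gamma")
  expect_error(simulation_config(n_genes = 20, complexes = list(
    list(genes = c(1, 2, 25), gamma = rep(0.5, 3)))), "gene indices")
  # edges must join distinct co-members of one complex
  cfg <- simulation_config(n_genes = 20, n_samples = 10,
                           complexes = list(list(genes = 1:4, gamma = rep(0.5, 4)),
                                            list(genes = 5:8, gamma = rep(0.5, 4))),
                           regulatory_edges = data.frame(x = 1, y = 5, delta = 1))
  expect_error(simulate_dataset(cfg), "co-members")
  cfg2 <- simulation_config(n_genes = 20, n_samples = 10,
                            complexes = list(list(genes = 1:4, gamma = rep(0.5, 4))),
                            regulatory_edges = data.frame(x = 2, y = 2, delta = 1))
  expect_error(simulate_dataset(cfg2), "distinct")
})

test_that("attenuation-score gap matches a Monte-Carlo oracle within 3 SE", {
  # 200 attenuated (gamma = 0.2) vs 1,800 pass-through genes, n = 300
  cfg <- clean_config(n_samples = 300, n_genes = 2000, n_complexes = 25,
                      complex_size_range = c(8, 8),
                      attenuated_gamma_range = c(0.2, 0.2),
                      rate_limiting_per_complex = 0,
                      dosage_slope_range = c(1, 1), seed = 17)
  ds <- simulate_dataset(cfg)
  att <- suppressMessages(
    feature_correlations(ds$cnv, ds$mrna, ds$protein, min_obs = 15))
  truth <- ds$truth$gene
  att_scores <- att$score[match(truth$gene[truth$attenuated], att$entity)]
  pass_scores <- att$score[match(truth$gene[!truth$attenuated], att$entity)]
  obs_gap <- mean(att_scores, na.rm = TRUE) - mean(pass_scores, na.rm = TRUE)

  # independent Monte-Carlo draw from the same generative equations
  mc_score <- function(gamma, n = 1e5) {
    cnv <- sample(-2:2, n, replace = TRUE, prob = c(0.05, 0.25, 0.40, 0.25, 0.05))
    t_ <- cnv + rnorm(n, 0, 0.5)
    p_ <- gamma * t_ + (1 - gamma) * rnorm(n, 0, 1) + rnorm(n, 0, 0.5)
    oracle_pearson(cnv, t_) - oracle_pearson(cnv, p_)
  }
  set.seed(1)
  reps <- replicate(4, mc_score(0.2) - mc_score(1))
  oracle_gap <- mean(reps)
  # scores of co-subunits are correlated through the shared latent complex
  # abundance, so the attenuated-group SE uses complex-level means; the
  # Monte-Carlo oracle contributes its own replicate SE
  cx_means <- tapply(att_scores, truth$complex[truth$attenuated], mean,
                     na.rm = TRUE)
  se_gap <- sqrt(var(cx_means) / length(cx_means) +
                 var(pass_scores, na.rm = TRUE) / length(pass_scores) +
                 var(reps) / length(reps))
  expect_gt(obs_gap, 0)
  expect_lt(abs(obs_gap - oracle_gap), 3 * se_gap)
})

test_that("buffered co-subunits correlate more strongly than random gene pairs", {
  ds <- simulate_dataset(clean_config(n_samples = 150, n_genes = 300,
                                      n_complexes = 12,
                                      complex_size_range = c(6, 6),
                                      rate_limiting_per_complex = 0, seed = 8))
  memb <- truth_membership(ds)
  pc <- pairwise_correlations(ds$protein, min_obs = 15)
  isets <- build_interaction_sets(complexes = memb,
                                  universe = rownames(ds$protein))
  key <- paste(pc$gene_a, pc$gene_b)
  pos <- key %in% paste(isets$complexes$gene_a, isets$complexes$gene_b)
  expect_gt(mean(pc$r[pos]), mean(pc$r[!pos]) + 0.2)
})

test_that("written datasets round-trip through the TSV readers", {
  ds <- simulate_dataset(simulation_config(n_samples = 20, n_genes = 30,
                                           n_complexes = 3,
                                           complex_size_range = c(4, 5),
                                           seed = 42))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_identical(read_omics(file.path(dir, "protein.tsv")), ds$protein)
  expect_identical(read_omics(file.path(dir, "cnv.tsv")), ds$cnv + 0)
  cov <- read_covariates(file.path(dir, "covariates.tsv"))
  expect_equal(cov$sample_id, ds$covariates$sample_id)
  memb <- read_complexes(file.path(dir, "complexes.tsv"))
  expect_setequal(memb$gene_id, truth_membership(ds)$gene_id)
})
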