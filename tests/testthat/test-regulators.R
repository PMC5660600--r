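# Two-stage residual regression: stage-one residuals, pair enumeration,
# F-tests with FDR, and the knockdown comparison.

test_that("residualize reproduces OLS residuals and degenerate designs", {
  t_ <- c(1, 2, 3, 4, 5, 6, 2, 4, 1, 3)
  p_ <- 2 * t_
  rp <- residualize(p_, t_)
  expect_lt(max(abs(rp$residuals)), 1e-10)
  expect_equal(rp$beta, 2, tolerance = 1e-10)

  # constant transcript: residual = centered protein, with a warning
  expect_warning(rp2 <- residualize(p_, rep(1, 10)), "constant")
  expect_equal(rp2$residuals, p_ - mean(p_), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(2)
  t3 <- rnorm(10)
  p3 <- 1.5 + 0.7 * t3 + rnorm(10, 0, 0.3)
  rp3 <- residualize(p3, t3)
  beta_or <- oracle_ols(cbind(1, t3), p3)
  expect_equal(rp3$residuals, p3 - beta_or[1] - beta_or[2] * t3,
               tolerance = 1e-10, ignore_attr = TRUE)
  # residual orthogonal to the centered transcript
  expect_lt(abs(sum(rp3$residuals * (t3 - mean(t3)))), 1e-6)

  p4 <- p3; p4[c(2, 5)] <- NA
  rp4 <- residualize(p4, t3, min_obs = 5)
  expect_true(all(is.na(rp4$residuals[c(2, 5)])))
  expect_identical(rp4$n, 8L)
  expect_error(residualize(p3[1:4], t3[1:4]), "complete pairs")
})

test_that("directed pair enumeration matches brute force and measurement filters", {
  memb <- tibble::tibble(complex_id = c("c1", "c1", "c1", "c2", "c2"),
                         gene_id = c("a", "b", "c", "c", "d"))
  all_measured <- c("a", "b", "c", "d")
  pairs <- enumerate_directed_pairs(memb, all_measured, all_measured)
  # brute force: c1 gives 6 ordered pairs among {a,b,c}; c2 gives (c,d),(d,c)
  expect_identical(nrow(pairs), 8L)
  expect_true(all(pairs$px != pairs$py))

  # x lacking predictor data drops x -> . but keeps . -> x as target
  pairs2 <- enumerate_directed_pairs(memb, all_measured, c("b", "c", "d"))
  expect_false("a" %in% pairs2$px)
  expect_true("a" %in% pairs2$py)

  one <- tibble::tibble(complex_id = "c", gene_id = c("x", "y", "z"))
  expect_identical(nrow(enumerate_directed_pairs(one, c("x", "y", "z"),
                                                 c("x", "y", "z"))), 6L)
})

test_that("single-predictor F equals t-squared with matching p-values", {
  set.seed(4)
  n <- 40
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  prot <- rbind(py = y, px = x)
  colnames(prot) <- sprintf("s%02d", 1:n)
  mrna <- rbind(py = rnorm(n), px = rnorm(n))
  dimnames(mrna) <- dimnames(prot)
  cnv <- rbind(py = sample(-2:2, n, TRUE), px = x)
  dimnames(cnv) <- dimnames(prot)
  pairs <- tibble::tibble(px = "px", py = "py")
  assoc <- suppressMessages(test_regulatory_pairs(prot, mrna, cnv, pairs, "cnv"))

  ry <- residualize(prot["py", ], mrna["py", ])$residuals
  fit <- stats::lm(ry ~ x)
  tval <- summary(fit)$coefficients[2, 3]
  pval <- summary(fit)$coefficients[2, 4]
  expect_equal(assoc$f_statistic, tval^2, tolerance = 1e-10)
  expect_equal(assoc$p_value, pval, tolerance = 1e-10)
  expect_identical(assoc$sign, ifelse(assoc$beta >= 0, "positive", "negative"))
})

test_that("BH adjustment equals the literal step-up procedure", {
  set.seed(9)
  p <- c(runif(40), runif(10, 0, 1e-3))
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  # and within an association table: fdr >= p always
  expect_true(all(oracle_bh(p) >= p))
})

test_that("null complexes give uniform p-values and almost no discoveries", {
  n_disc <- 0
  for (s in 1:3) {
    ds <- simulate_dataset(simulation_config(
      n_samples = 150, n_genes = 120, n_complexes = 20,
      complex_size_range = c(6, 6), missing_rate = 0.05, seed = 100 + s))
    memb <- truth_membership(ds)
    pairs <- enumerate_directed_pairs(memb, rownames(ds$protein),
                                      rownames(ds$cnv))
    assoc <- suppressMessages(
      test_regulatory_pairs(ds$protein, ds$mrna, ds$cnv, pairs, "cnv"))
    n_disc <- n_disc + sum(assoc$significant)
    if (s == 1) {
      ks <- suppressWarnings(stats::ks.test(assoc$p_value, "punif"))
      expect_gt(ks$p.value, 0.01)
    }
  }
  expect_lte(n_disc / 3, 1)
})

test_that("implanted positive and negative edges are recovered with correct signs", {
  cxs <- c(list(list(genes = 1:6, gamma = c(1, rep(0.2, 5)))),
           lapply(1:4, function(k) list(genes = 6 + (6 * (k - 1) + 1):(6 * k),
                                        gamma = c(1, rep(0.2, 5)))))
  cfg <- simulation_config(
    n_samples = 282, n_genes = 40, complexes = cxs, missing_rate = 0.1,
    regulatory_edges = data.frame(x = c(1, 1), y = c(2, 3),
                                  delta = c(0.47, -0.47)), seed = 12)
  ds <- simulate_dataset(cfg)
  memb <- truth_membership(ds)
  pairs <- enumerate_directed_pairs(memb, rownames(ds$protein), rownames(ds$cnv))
  assoc <- suppressMessages(
    test_regulatory_pairs(ds$protein, ds$mrna, ds$cnv, pairs, "cnv"))
  pos <- assoc[assoc$px == "g0001" & assoc$py == "g0002", ]
  neg <- assoc[assoc$px == "g0001" & assoc$py == "g0003", ]
  expect_true(pos$significant && pos$sign == "positive")
  expect_true(neg$significant && neg$sign == "negative")
})

test_that("transcript support annotation flags dual-evidence associations", {
  a_cnv <- tibble::tibble(px = c("a", "b"), py = c("x", "y"),
                          significant = c(TRUE, TRUE))
  a_t <- tibble::tibble(px = c("a", "b"), py = c("x", "y"),
                        significant = c(TRUE, FALSE))
  out <- add_transcript_support(a_cnv, a_t)
  expect_identical(out$transcript_support, c(TRUE, FALSE))
})

test_that("knockdown comparison reproduces Spearman's rho", {
  assoc <- tibble::tibble(px = paste0("x", 1:8), py = paste0("y", 1:8),
                          beta = c(0.9, 0.4, -0.2, 0.7, -0.5, 0.1, 0.3, -0.8))
  kd <- tibble::tibble(px = assoc$px, py = assoc$py,
                       effect = c(0.8, 0.1, -0.1, 0.9, -0.6, 0.2, 0.05, -0.7))
  res <- compare_to_knockdowns(assoc, kd)
  expect_equal(res$rho, oracle_spearman(assoc$beta, kd$effect),
               tolerance = 1e-12)
  expect_identical(res$n_overlap, 8L)

  kd_same <- dplyr::mutate(kd, effect = assoc$beta)
  expect_equal(compare_to_knockdowns(assoc, kd_same)$rho, 1)
  kd_rev <- dplyr::mutate(kd, effect = -assoc$beta)
  expect_equal(compare_to_knockdowns(assoc, kd_rev)$rho, -1)
  expect_error(compare_to_knockdowns(assoc[1:2, ], kd), "overlapping")
})
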