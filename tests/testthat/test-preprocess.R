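# CPM filtering, coverage, confounder regression, presence filtering and
# KDE-mode centering.

make_counts <- function(values, libnames = NULL) {
  m <- values
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) {
    colnames(m) <- if (is.null(libnames)) sprintf("s%02d", seq_len(ncol(m))) else libnames
  }
  m
}

test_that("cpm filter drops lowly expressed genes and returns log2(CPM + 0.5)", {
  counts <- make_counts(rbind(
    zero = c(0, 0),
    low = c(1, 1),          # CPM 1 and 0.5 -> mean 0.75 <= 1, excluded
    high = c(1e6 - 1, 2e6 - 1)
  ))
  colnames(counts) <- c("a", "b")
  out <- cpm_filter_log(counts)
  expect_identical(rownames(out), "high")
  cpm_high <- c((1e6 - 1) / 1e6, (2e6 - 1) / 2e6) * 1e6
  expect_equal(unname(out["high", ]), log2(cpm_high + 0.5), tolerance = 1e-12)

  # every gene comfortably expressed -> none excluded, samples in order
  big <- make_counts(matrix(100, 5, 3))
  expect_identical(dim(cpm_filter_log(big)), c(5L, 3L))
  expect_identical(colnames(cpm_filter_log(big)), colnames(big))
})

test_that("zero library size is rejected naming the sample", {
  counts <- make_counts(matrix(c(1, 2, 0, 0), 2, 2), libnames = c("ok", "empty"))
  expect_error(cpm_filter_log(counts), "empty")
})

test_that("jaccard coverage handles identity, disjoint and partial overlap", {
  expect_equal(coverage_jaccard(letters[1:5], letters[1:5]), 1)
  expect_equal(coverage_jaccard(letters[1:3], letters[4:6]), 0)
  expect_equal(coverage_jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(coverage_jaccard(character(0), character(0)), "empty")
})

test_that("confounder regression removes a pure batch effect and keeps the mean", {
  cov <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                        batch = rep(c("A", "B"), each = 5))
  m <- matrix(1 + 2 * (cov$batch == "B"), nrow = 1,
              dimnames = list("g1", cov$sample_id))
  out <- regress_out_covariates(m, cov)
  expect_equal(unname(out[1, ]), rep(1, 10), tolerance = 1e-8)

  # covariate numerically orthogonal to the gene leaves it unchanged
  cov2 <- tibble::tibble(sample_id = sprintf("s%02d", 1:8),
                         x = rep(c(-1, 1), 4))
  g <- rep(c(5, 5, 7, 7), 2)  # orthogonal to x
  m2 <- matrix(g, nrow = 1, dimnames = list("g1", cov2$sample_id))
  expect_equal(unname(regress_out_covariates(m2, cov2)[1, ]), g,
               tolerance = 1e-8)
})

test_that("residuals are orthogonal to every design column on complete data", {
  set.seed(1)
  cov <- tibble::tibble(sample_id = sprintf("s%03d", 1:60),
                        age = runif(60, 30, 80),
                        gender = sample(c("f", "m"), 60, TRUE),
                        tumour_type = sample(c("x", "y", "z"), 60, TRUE))
  m <- matrix(rnorm(10 * 60), 10, 60,
              dimnames = list(sprintf("g%02d", 1:10), cov$sample_id))
  out <- regress_out_covariates(m, cov)
  design <- stats::model.matrix(~ age + gender + tumour_type,
                                data = as.data.frame(cov))
  centered <- out - rowMeans(out)
  for (j in 2:ncol(design)) {
    expect_lt(max(abs(centered %*% (design[, j] - mean(design[, j])))), 1e-6)
  }
})

test_that("degenerate covariates and sparse genes are handled with warnings", {
  cov <- tibble::tibble(sample_id = sprintf("s%02d", 1:6),
                        tech = rep("only_one", 6),
                        age = c(40, 50, 60, 45, 55, 65))
  m <- matrix(rnorm(6), 1, 6, dimnames = list("g1", cov$sample_id))
  expect_warning(regress_out_covariates(m, cov), "single level")

  m2 <- matrix(c(1, 2, NA, NA, NA, NA), 1, 6,
               dimnames = list("g1", cov$sample_id))
  expect_warning(
    expect_warning(out <- regress_out_covariates(m2, cov), "single level"),
    "uncorrected")
  expect_equal(out, m2)
})

test_that("covariate associations vanish from the top principal components", {
  ds <- simulate_dataset(simulation_config(n_samples = 120, n_genes = 300,
                                           n_complexes = 10, missing_rate = 0,
                                           seed = 31))
  corrected <- regress_out_covariates(ds$mrna, ds$covariates)
  pcs <- prcomp(t(corrected), center = TRUE, scale. = FALSE)$x[, 1:10]
  design <- stats::model.matrix(~ age + gender + tumour_type + technology,
                                data = as.data.frame(ds$covariates))[, -1]
  for (j in seq_len(ncol(design))) {
    expect_lt(max(abs(cor(pcs, design[, j]))), 0.1)
  }
})

test_that("presence filter applies a strict >= threshold without reordering", {
  m <- matrix(rnorm(300), 3, 100,
              dimnames = list(c("keep_all", "at49", "at50"), sprintf("s%03d", 1:100)))
  m["at49", 1:51] <- NA  # 49% present
  m["at50", 1:50] <- NA  # exactly 50% present
  out <- presence_filter(m, 0.5)
  expect_identical(rownames(out), c("keep_all", "at50"))
  expect_identical(colnames(out), colnames(m))
  expect_identical(presence_filter(m[1, , drop = FALSE]), m[1, , drop = FALSE])
  expect_error(presence_filter(m["at49", , drop = FALSE], 0.9), "every gene")

  # brute-force recount on random missingness
  set.seed(4)
  m2 <- matrix(rnorm(50 * 40), 50, 40,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:40)))
  m2[sample(length(m2), 600)] <- NA
  keep_oracle <- apply(m2, 1, function(r) sum(!is.na(r)) / 40 >= 0.5)
  expect_identical(rownames(presence_filter(m2, 0.5)),
                   rownames(m2)[keep_oracle])
})

test_that("kde centering puts the dominant mode at zero and is idempotent", {
  set.seed(7)
  sym <- rnorm(400)
  expect_lt(abs(mean(sym - kde_mode(sym))), 0.15)

  bim <- c(rnorm(300, 5, 0.3), rnorm(100, 0, 0.3))
  expect_lt(abs(kde_mode(bim) - oracle_kde_mode(bim)), 0.02)
  expect_gt(kde_mode(bim), 4.5)  # mode, not the mean (~3.75)

  m <- rbind(a = sym, b = bim)
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  once <- kde_center(m)
  twice <- kde_center(once)
  expect_lt(max(abs(once - twice)), 1e-6)

  cst <- matrix(3, 1, 6, dimnames = list("c", sprintf("s%d", 1:6)))
  expect_equal(unname(kde_center(cst)[1, ]), rep(0, 6))
})

test_that("omics and GMT writers round-trip bit-exactly", {
  set.seed(12)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(sprintf("g%02d", 1:6), sprintf("s%02d", 1:10)))
  m[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics(m, path)
  expect_identical(read_omics(path), m)

  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  back <- read_gmt(gmt)
  expect_identical(back$alpha, sets$alpha)
  expect_identical(back$beta, sets$beta)
})
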