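# Synthetic multi-omics generator. Emulates the statistical structure the
# attenuation analysis assumes: discrete CNV states propagating linearly to
# mRNA, protein tracking mRNA except for complex subunits buffered toward a
# shared latent complex abundance, implanted directed rate-limiting edges,
# additive covariate confounding, and MCAR protein missingness.

#' Configuration for the synthetic multi-omics generator
#'
#' Defines the generative model behind [simulate_dataset()]. Per sample j and
#' gene i, CNV states are drawn from `cnv_state_probs` on \{-2,...,2\};
#' transcript abundance is `T = mu_i + a_i * CNV + covariate shift + N(0,
#' mrna_noise_sd^2)` with per-gene dosage slope `a_i` uniform on
#' `dosage_slope_range`; for genes outside complexes protein tracks mRNA
#' (`P = nu_i + T + noise`), while a complex subunit with buffering factor
#' `gamma < 1` is pulled toward a latent per-sample complex abundance
#' `C_k ~ N(0, complex_sd^2)` shared by its co-members:
#' `P = nu_i + gamma * (T - mu_i) + (1 - gamma) * C_k + noise`.
#' Each directed regulatory edge `(x, y, delta)` adds
#' `delta * (CNV_x - mean(CNV_x))` to the protein of y, modelling a
#' rate-limiting subunit x whose dosage constrains partner y.
#'
#' @param n_samples,n_genes Cohort and gene-universe size. Defaults (282
#'   samples, 2,000 genes) give a desk-scale cohort of the size used for
#'   tumour panels with matched CNV/mRNA/protein measurements.
#' @param cnv_state_probs Probabilities of GISTIC-like states -2,-1,0,1,2;
#'   must be non-negative and sum to 1.
#' @param dosage_slope_range Interval for the per-gene mRNA~CNV slope.
#' @param mrna_noise_sd,protein_noise_sd Gaussian noise SDs on mRNA / protein.
#' @param complexes Optional explicit complex catalog: a list whose elements
#'   are lists with `genes` (integer gene indices) and `gamma` (per-subunit
#'   buffering factors in `[0, 1]`, 1 = no buffering). When `NULL`, a catalog
#'   is generated from `n_complexes`, `complex_size_range`,
#'   `attenuated_gamma_range` and `rate_limiting_per_complex`.
#' @param n_complexes,complex_size_range Number of disjoint complexes and the
#'   range of subunit counts when generating the catalog.
#' @param attenuated_gamma_range Buffering factors for attenuated subunits are
#'   drawn uniformly from this interval.
#' @param rate_limiting_per_complex How many subunits per generated complex
#'   keep `gamma = 1` (pass-through, rate-limiting candidates).
#' @param complex_sd SD of the latent per-sample complex abundance `C_k`
#'   (independent of every CNV, so buffering strictly reduces r(CNV, protein)
#'   without creating spurious CNV associations).
#' @param regulatory_edges Optional data frame with integer columns `x`, `y`
#'   (gene indices, distinct co-members of some complex) and numeric `delta`.
#' @param covariate_effects Named list of effect scales: `age` (per-year slope
#'   on mRNA), `gender`, `tumour_type` (per-level shifts on mRNA, drawn
#'   `N(0, scale^2)` per level) and `technology` (per-level shift on protein).
#' @param sample_attenuation Optional list `(fraction, gamma)` planting a
#'   high-buffering subgroup: in a random `fraction` of samples every complex
#'   subunit uses buffering factor `gamma`, overriding its per-gene value.
#' @param missing_rate Probability that a protein entry is masked (MCAR);
#'   must be in `[0, 0.5)` so presence filtering retains genes by default.
#' @param seed Integer seed; equal configs and seeds give identical datasets.
#' @return A validated object of class `simulation_config`.
#' @seealso [simulate_dataset()]
#' @export
simulation_config <- function(n_samples = 282,
                              n_genes = 2000,
                              cnv_state_probs = c(0.05, 0.25, 0.40, 0.25, 0.05),
                              dosage_slope_range = c(0.8, 1.2),
                              mrna_noise_sd = 0.5,
                              protein_noise_sd = 0.5,
                              complexes = NULL,
                              n_complexes = 30,
                              complex_size_range = c(4, 10),
                              attenuated_gamma_range = c(0.15, 0.25),
                              rate_limiting_per_complex = 1,
                              complex_sd = 1,
                              regulatory_edges = NULL,
                              covariate_effects = list(age = 0.005, gender = 0.2,
                                                       tumour_type = 0.3,
                                                       technology = 0.3),
                              sample_attenuation = NULL,
                              missing_rate = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    cnv_state_probs = cnv_state_probs,
    dosage_slope_range = dosage_slope_range,
    mrna_noise_sd = mrna_noise_sd, protein_noise_sd = protein_noise_sd,
    complexes = complexes, n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    attenuated_gamma_range = attenuated_gamma_range,
    rate_limiting_per_complex = as.integer(rate_limiting_per_complex),
    complex_sd = complex_sd,
    regulatory_edges = regulatory_edges,
    covariate_effects = covariate_effects,
    sample_attenuation = sample_attenuation,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  p <- cfg$cnv_state_probs
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("`cnv_state_probs` must be 5 non-negative probabilities summing to 1")
  }
  if (cfg$n_samples < 2L) abort("`n_samples` must be at least 2")
  if (cfg$n_genes < 2L) abort("`n_genes` must be at least 2")
  if (cfg$mrna_noise_sd < 0) abort("`mrna_noise_sd` must be non-negative")
  if (cfg$protein_noise_sd < 0) abort("`protein_noise_sd` must be non-negative")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1)")
  }
  if (any(cfg$attenuated_gamma_range < 0) || any(cfg$attenuated_gamma_range > 1)) {
    abort("`attenuated_gamma_range`: gamma must lie in [0, 1]")
  }
  if (!is.null(cfg$complexes)) {
    for (cx in cfg$complexes) {
      if (is.null(cx$genes) || is.null(cx$gamma) ||
          length(cx$genes) != length(cx$gamma)) {
        abort("`complexes` elements need matching `genes` and `gamma` fields")
      }
      if (any(cx$gamma < 0 | cx$gamma > 1)) {
        abort("`complexes`: gamma must lie in [0, 1]")
      }
      if (any(cx$genes < 1L | cx$genes > cfg$n_genes)) {
        abort("`complexes`: gene indices outside 1..n_genes")
      }
    }
  }
  if (!is.null(cfg$sample_attenuation)) {
    sa <- cfg$sample_attenuation
    if (is.null(sa$fraction) || is.null(sa$gamma) ||
        sa$fraction < 0 || sa$fraction > 1 || sa$gamma < 0 || sa$gamma > 1) {
      abort("`sample_attenuation` needs `fraction` and `gamma` in [0, 1]")
    }
  }
  cfg
}

# Realize the complex catalog as a per-gene gamma vector + assignment table.
realize_complexes <- function(cfg) {
  if (is.null(cfg$complexes)) {
    sizes <- sample(seq(cfg$complex_size_range[1], cfg$complex_size_range[2]),
                    cfg$n_complexes, replace = TRUE)
    if (sum(sizes) > cfg$n_genes) {
      abort("`n_complexes`/`complex_size_range`: complexes need more genes than `n_genes`")
    }
    members <- sample(cfg$n_genes, sum(sizes))
    idx <- split(members, rep(seq_along(sizes), sizes))
    complexes <- lapply(idx, function(g) {
      gam <- runif(length(g), cfg$attenuated_gamma_range[1],
                   cfg$attenuated_gamma_range[2])
      n_rl <- min(cfg$rate_limiting_per_complex, length(g))
      if (n_rl > 0) gam[seq_len(n_rl)] <- 1
      list(genes = g, gamma = gam)
    })
  } else {
    complexes <- cfg$complexes
  }
  assignment <- dplyr::bind_rows(lapply(seq_along(complexes), function(k) {
    tibble(complex = k, gene_idx = as.integer(complexes[[k]]$genes),
           gamma = complexes[[k]]$gamma)
  }))
  if (anyDuplicated(assignment$gene_idx)) {
    abort("`complexes`: overlapping membership not supported (a gene has one gamma)")
  }
  list(complexes = complexes, assignment = assignment)
}

#' Simulate a multi-omics dataset with known attenuation ground truth
#'
#' Draws CNV, mRNA and protein matrices plus a covariate table from the
#' generative model described in [simulation_config()], and records the
#' ground truth (per-gene buffering factors, attenuated-gene flags, complex
#' assignments, implanted regulatory edges, planted high-buffering samples).
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset` with elements `cnv`, `mrna`,
#'   `protein` (genes x samples matrices; protein has `NA` entries),
#'   `covariates` (tibble: sample_id, age, gender, tumour_type, technology)
#'   and `truth` (list: `gene` tibble with gamma/attenuated/complex,
#'   `edges`, `attenuated_samples`, `config`).
#' @examples
#' ds <- simulate_dataset(simulation_config(n_samples = 40, n_genes = 100,
#'                                          n_complexes = 4, seed = 7))
#' dim(ds$protein)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  withr::local_seed(config$seed)

  ng <- config$n_genes
  ns <- config$n_samples
  genes <- sprintf("g%04d", seq_len(ng))
  samples <- sprintf("s%03d", seq_len(ns))

  cat_cx <- realize_complexes(config)
  gamma <- rep(1, ng)
  gamma[cat_cx$assignment$gene_idx] <- cat_cx$assignment$gamma
  complex_of <- rep(NA_integer_, ng)
  complex_of[cat_cx$assignment$gene_idx] <- cat_cx$assignment$complex

  edges <- config$regulatory_edges
  if (!is.null(edges)) {
    edges <- as_tibble(edges)
    if (!all(c("x", "y", "delta") %in% names(edges))) {
      abort("`regulatory_edges` needs columns x, y, delta")
    }
    if (any(edges$x < 1 | edges$x > ng | edges$y < 1 | edges$y > ng)) {
      abort("`regulatory_edges`: gene indices outside 1..n_genes")
    }
    if (any(edges$x == edges$y)) {
      abort("`regulatory_edges`: x and y must be distinct genes")
    }
    same_cx <- !is.na(complex_of[edges$x]) &
      complex_of[edges$x] == complex_of[edges$y]
    if (!all(same_cx)) {
      abort("`regulatory_edges`: x and y must be co-members of the same complex")
    }
  }

  covariates <- tibble(
    sample_id = samples,
    age = round(runif(ns, 30, 85)),
    gender = sample(c("female", "male"), ns, replace = TRUE),
    tumour_type = sample(c("BRCA", "HGSC", "COREAD"), ns, replace = TRUE),
    technology = sample(c("itraq", "label_free"), ns, replace = TRUE)
  )
  eff <- config$covariate_effects
  lvl_shift <- function(values, scale) {
    lv <- sort(unique(values))
    co <- rnorm(length(lv), 0, scale %||% 0)
    co[match(values, lv)]
  }
  shift_mrna <- (eff$age %||% 0) * (covariates$age - mean(covariates$age)) +
    lvl_shift(covariates$gender, eff$gender) +
    lvl_shift(covariates$tumour_type, eff$tumour_type)
  shift_protein <- lvl_shift(covariates$technology, eff$technology)

  cnv <- matrix(sample(-2:2, ng * ns, replace = TRUE, prob = config$cnv_state_probs),
                nrow = ng, dimnames = list(genes, samples))
  mu <- rnorm(ng, 0, 0.5)
  nu <- rnorm(ng, 0, 0.5)
  slope <- runif(ng, config$dosage_slope_range[1], config$dosage_slope_range[2])

  mrna <- mu + slope * cnv +
    matrix(shift_mrna, ng, ns, byrow = TRUE) +
    matrix(rnorm(ng * ns, 0, config$mrna_noise_sd), ng, ns)
  dimnames(mrna) <- list(genes, samples)

  # latent complex abundances, one per complex per sample
  n_cx <- length(cat_cx$complexes)
  c_latent <- matrix(rnorm(n_cx * ns, 0, config$complex_sd), n_cx, ns)

  attenuated_samples <- character(0)
  gamma_eff <- matrix(gamma, ng, ns)  # per-gene, per-sample effective gamma
  if (!is.null(config$sample_attenuation)) {
    sa <- config$sample_attenuation
    planted <- sample(ns, round(sa$fraction * ns))
    attenuated_samples <- samples[sort(planted)]
    member <- !is.na(complex_of)
    gamma_eff[member, planted] <- sa$gamma
  }

  protein <- nu + mrna +
    matrix(rnorm(ng * ns, 0, config$protein_noise_sd), ng, ns)
  member_idx <- which(!is.na(complex_of))
  if (length(member_idx)) {
    g <- gamma_eff[member_idx, , drop = FALSE]
    protein[member_idx, ] <- nu[member_idx] +
      g * (mrna[member_idx, , drop = FALSE] - mu[member_idx]) +
      (1 - g) * c_latent[complex_of[member_idx], , drop = FALSE] +
      matrix(rnorm(length(member_idx) * ns, 0, config$protein_noise_sd),
             length(member_idx), ns)
  }
  dimnames(protein) <- list(genes, samples)
  protein <- protein + matrix(shift_protein, ng, ns, byrow = TRUE)

  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      x <- edges$x[e]; y <- edges$y[e]
      protein[y, ] <- protein[y, ] + edges$delta[e] * (cnv[x, ] - mean(cnv[x, ]))
    }
  }

  if (config$missing_rate > 0) {
    mask <- matrix(runif(ng * ns) < config$missing_rate, ng, ns)
    protein[mask] <- NA_real_
  }

  truth_gene <- tibble(
    gene = genes, gamma = gamma,
    attenuated = gamma < 1 & !is.na(complex_of),
    complex = complex_of,
    mu = mu, nu = nu, dosage_slope = slope
  )
  truth_edges <- if (is.null(edges)) {
    tibble(x = character(0), y = character(0), delta = numeric(0))
  } else {
    tibble(x = genes[edges$x], y = genes[edges$y], delta = edges$delta)
  }

  structure(list(
    cnv = cnv, mrna = mrna, protein = protein, covariates = covariates,
    truth = list(gene = truth_gene, edges = truth_edges,
                 attenuated_samples = attenuated_samples, config = config)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d genes x %d samples; %d complex subunits (%d attenuated); %d regulatory edges; %.1f%% protein entries missing\n",
    nrow(x$cnv), ncol(x$cnv), sum(!is.na(x$truth$gene$complex)),
    sum(x$truth$gene$attenuated), nrow(x$truth$edges),
    100 * mean(is.na(x$protein))))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `cnv.tsv`, `mrna.tsv`, `protein.tsv` (genes x samples, `NA` for
#' missing), `covariates.tsv`, `complexes.tsv` (two-column membership:
#' complex_id, gene_id) and `truth.json`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics(ds$cnv, file.path(dir, "cnv.tsv"))
  write_omics(ds$mrna, file.path(dir, "mrna.tsv"))
  write_omics(ds$protein, file.path(dir, "protein.tsv"))
  readr::write_tsv(ds$covariates, file.path(dir, "covariates.tsv"))
  memb <- ds$truth$gene |>
    filter(!is.na(.data$complex)) |>
    mutate(complex_id = sprintf("cx%03d", .data$complex)) |>
    select(complex_id, gene_id = "gene")
  readr::write_tsv(memb, file.path(dir, "complexes.tsv"))
  truth <- list(
    gene = ds$truth$gene,
    edges = ds$truth$edges,
    attenuated_samples = ds$truth$attenuated_samples,
    seed = ds$truth$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
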