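---
title: "Quantifying post-transcriptional attenuation of copy-number effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-transcriptional attenuation of copy-number effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvbuffer)
```

## The question and the model

Gene-dosage changes in tumours propagate along the central dogma: a copy
gained at the DNA level typically raises the transcript, and the transcript
raises the protein. The interesting biology sits where the chain breaks.
Protein-complex subunits are produced in stoichiometric excess at the mRNA
level when amplified, but free subunits are unstable and degraded, so the
protein tracks the *complex*, not the gene's own dosage. `cnvbuffer`
quantifies this with per-gene statistics that need nothing beyond matched
genes × samples matrices:

* `r_cnv_mrna` — Pearson correlation between the GISTIC-like CNV state
  (integers −2..2, treated as numeric) and expression, across samples;
* `r_cnv_protein` — same against protein abundance;
* the **attenuation score** `r_cnv_mrna − r_cnv_protein`.

Scores live in [−2, 2]; genuinely buffered genes sit well above zero while
pass-through genes scatter around a small positive baseline (protein
measurements are noisier than transcript measurements, which inflates the
baseline slightly — an assumption worth keeping in mind, since differential
measurement error is indistinguishable from mild buffering in this design).
A two-component Gaussian mixture on the scores separates the attenuated
component (larger mean) from the background. The same machinery transposes
to samples: correlating across the genes measured in one sample yields the
sample's **attenuation potential**, ranking tumours by how strongly they
buffer dosage proteome-wide.

## Preprocessing assumptions

The correlations are computed on pairwise-complete observations, so the
protein matrix may contain missing entries; genes with fewer than `min_obs`
(default 15) complete pairs for either correlation are excluded from
scoring. Fifteen pairs keep the correlation estimate's SE below ~0.27 —
noisy but rankable — while discarding genes whose estimates would be
dominated by a handful of samples.

Upstream of the correlations:

* `cpm_filter_log()` removes genes with mean CPM ≤ 1 and returns
  log2(CPM + 0.5). Full library-scale normalisation (TMM, precision
  weights) is deliberately out of scope: the downstream statistics are
  correlations, which are invariant to per-sample scaling.
* `regress_out_covariates()` fits, per gene, OLS on one-hot-coded
  categorical covariates (tumour type, gender, measurement technology) plus
  continuous age, and keeps residual + fitted intercept. Retaining the
  intercept keeps corrected abundances on their original scale; whether to
  re-centre to zero is genuinely open, and the intercept choice is the more
  conservative of the two (it changes nothing downstream, as every
  downstream statistic is correlation- or residual-based).
* `presence_filter()` keeps genes measured in ≥ 50% of samples (the usual
  mass-spectrometry presence rule).
* `kde_center()` subtracts the mode of a Gaussian kernel density estimate
  (Silverman's rule-of-thumb bandwidth, 2,048-point grid) per gene.
  Mode-centering rather than mean-centering is a judgement call: abundance
  distributions are skewed and occasionally bimodal, and the mode is the
  natural "typical sample" anchor. The KDE mode is also used to centre the
  score vector before enrichment ranking, so the ranking metric is zero at
  its bulk.

## Numerical choices

* **Mixture fitting.** `classify_attenuation()` uses model-based
  hierarchical initialisation followed by EM (unequal variances, with an
  equal-variance retry when a cluster degenerates to a point mass), which
  is deterministic without needing a seed — preferable to k-means restarts,
  whose result can depend on the restart RNG. The `seed` argument is kept
  and recorded in the fit report for bookkeeping. Labels come from the
  posterior: a point is `attenuated` only if its posterior exceeds 0.5, so
  exact ties go to the background (conservative). Near-constant score
  vectors (SD < 1e−8) trigger a single-cluster fallback with every label
  `background` and a warning.
* **GSEA.** Weighted KS running sum with weight exponent 1 (hit increments
  ∝ |score|, uniform miss decrements). The permutation null randomises
  *set membership* — an attenuation ranking has no phenotype labels to
  permute — and the two-sided p compares |ES| with +1 smoothing, so p is
  floored at 1/(n_perm + 1) and never zero. Ranking ties are broken by gene
  id for determinism.
* **AROC.** Computed by the rank-sum (Mann–Whitney) identity with midranks
  for ties; the test suite verifies it equals trapezoidal ROC integration
  on every instance. Because non-interacting pairs vastly outnumber
  interacting ones, negatives are drawn as five randomized sets matched in
  size to the positives — the number of draws is conventional; the size
  matching is this package's choice, made so each draw is a balanced
  classification problem.
* **Regulator regression.** Both stages include intercepts. Residuals are
  not re-standardised before stage two, so slopes are in protein-abundance
  units per CNV state. The F statistic against the intercept-only model
  equals t² for the single predictor; FDR is computed separately for the
  CNV-predictor and transcript-predictor families, which are separate
  hypothesis collections. Pairs with a zero-variance predictor or fewer
  than 10 complete observations are skipped and counted.
* **Signature benchmark.** Stratified 70/30 splits; per-gene ANOVA F with
  BH FDR < 5% for feature selection on the training fold only; ridge
  logistic regression with penalty chosen from {0.01, 0.1, 1, 10} by
  stratified 5-fold CV within the training fold. Splits where no feature
  survives fall back to AROC 0.5 and are counted, which keeps the null
  calibration honest rather than optimistic.

## What the generator emulates — and what it does not

`simulation_config()` encodes the generative stand-in used everywhere in
the tests. Per sample *j*, gene *i*:

* CNV states are categorical on \{−2..2\} with probabilities
  (0.05, 0.25, 0.40, 0.25, 0.05) — mostly diploid, alterations common,
  extreme events rare.
* mRNA: `T = μᵢ + aᵢ·CNV + covariate shift + N(0, 0.5²)`, slope `aᵢ`
  uniform on [0.8, 1.2] (dosage propagates roughly one-to-one in log
  space).
* Protein: non-subunits track mRNA plus noise (`σ_P = 0.5`); a subunit of
  complex *k* with buffering factor γ follows
  `νᵢ + γ(T − μᵢ) + (1 − γ)·C_k + N(0, 0.5²)` where `C_k ~ N(0, 1)` is a
  latent per-sample complex abundance shared by co-members and independent
  of every CNV — so buffering strictly lowers r(CNV, protein) without
  creating spurious CNV associations, and simultaneously creates the
  protein-specific co-regulation of complex partners.
* Directed rate-limiting edges (x, y, δ) add `δ·(CNV_x − mean)` to the
  protein of y.
* Covariates shift mRNA (age, gender, tumour type) and protein
  (technology) additively, giving the confounder regression something real
  to remove; protein entries are masked MCAR.

Defaults are a 282-sample, 2,000-gene cohort with 30 complexes of 4–10
subunits, attenuated γ drawn from [0.15, 0.25] and one pass-through
(γ = 1, rate-limiting candidate) subunit per complex. The sample count
matches the tumour cohorts this analysis is designed for; the gene count is
a desk-scale compromise. With these defaults the gap between attenuated and
pass-through mean scores is ≈ 0.6, which is what makes the mixture recovery
checks sharp; the γ range was chosen once for that design and is not a
tuning knob.

A planted high-buffering subgroup (`sample_attenuation = list(fraction,
gamma)`) overrides γ for all complex subunits in a random fraction of
samples. A per-sample γ override is used rather than inflating the latent
complex variance because it is a direct, interpretable knob that produces
the same qualitative structure — samples whose proteome decouples from
dosage.

The generator deliberately omits: continuous dosage (CNV enters as the
discrete state, as it would from GISTIC output), informative missingness,
translation-vs-degradation mechanisms, ubiquitination dynamics,
chromosome-arm events, and tumour purity/ploidy structure. Passing tests
therefore demonstrate correctness of the statistical machinery under a
linear-Gaussian dosage model, not robustness to every failure mode of real
proteogenomic data — in particular, real attenuation calls are sensitive to
differential measurement error and to complex-catalog quality in ways the
synthetic truth cannot expose.

## Problem sizes in the test-suite

The validation suite runs the default 282 × 2,000 cohort for mixture
recovery, 100 seeds of a 30-gene/5-complex design for implanted-edge power,
50 seeds of a 72-gene design with 5% true edges for empirical-FDR control,
and 100-split benchmarks on a 300 × 200 expression matrix; these sizes give
each check enough resolution to fail informatively while keeping a full run
in minutes.

## Limitations

* The attenuation score conflates buffering with differential measurement
  noise; the mixture's background component absorbs part of this, but
  absolute attenuated fractions depend on the noise regime.
* GISTIC states are treated as numeric in correlations and regressions;
  with the state distribution concentrated on \{−1, 0, 1\} this is close to
  linear, but heavily amplified loci stretch the scale.
* The regulator test inherits the usual caveat of residual regressions:
  stage-one residuals are estimates, so stage-two p-values are mildly
  optimistic at small n (the calibration tests bound this empirically at
  the cohort sizes used).
* Interaction negatives are sampled from all non-positive pairs for the set
  under evaluation; pairs positive in *another* catalog may therefore
  appear among negatives, which biases AROCs slightly downward.
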