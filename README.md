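# cnvbuffer

Somatic copy-number variation (CNV) is pervasive in tumours, but a gene
gained or lost at the DNA level is not necessarily gained or lost at the
protein level. In matched CNV / transcriptome / proteome cohorts, dosage
changes usually propagate to mRNA, yet for a sizeable fraction of
proteins — protein-complex subunits above all — the effect is attenuated
post-transcriptionally, most plausibly by degradation of subunits that
exceed the stoichiometry of their complex. `cnvbuffer` implements the full
analysis for quantifying this buffering in genes × samples omics matrices,
together with a synthetic multi-omics generator with known ground truth so
that every stage can be validated at desk scale.

It is aimed at computational biologists with matched CNV (GISTIC-style
thresholded states in −2..2), expression and (sparse) protein abundance
tables, plus a complex catalog (CORUM-like membership lists).

## What it computes

**Attenuation score.** For gene *i* (or, transposed, for sample *j*):

```
score_i = r(CNV_i, mRNA_i) − r(CNV_i, protein_i)
```

with pairwise-complete Pearson correlations across samples (across genes for
the per-sample *attenuation potential*). Positive scores mean dosage reaches
the transcript but not the protein. A two-component Gaussian mixture
separates attenuated entities (higher-mean component) from the background; a
stringent call additionally requires |score| > 0.3.

**Enrichment.** Scores are mode-centred with a Gaussian KDE and tested
against gene-set collections by weighted Kolmogorov–Smirnov GSEA with a
gene-set-membership permutation null (1,000 permutations, BH FDR).

**Co-regulation.** All `choose(n, 2)` pairwise abundance correlations per
molecular level; complex/functional/signaling/metabolic interaction pairs
are evaluated as classifiers by AROC against five randomized size-matched
negative sets.

**Rate-limiting subunits.** Two-stage residual regression per directed
complex co-member pair (x → y):

```
P_y  = β·T_y + ψ            (stage 1: remove the transcript component)
P_y' = β₂·CNV_x + ψ         (stage 2: residual vs the partner's dosage)
```

scored by an F test (df 1, n − 2) and BH FDR per predictor family, with the
transcript-of-x variant as corroborating evidence, and a Spearman comparison
against knockdown effect tables.

**Attenuation-potential signature.** Per-gene correlation of expression with
the per-sample potential; sample scoring by correlation with the signature;
cross-validated L2-logistic benchmark (70/30 splits, ANOVA-F + FDR feature
selection); per-drug response association by single linear regressions.

## Worked example

```r
library(cnvbuffer)

ds <- simulate_dataset(simulation_config(n_samples = 120, n_genes = 500,
                                         n_complexes = 12, seed = 42))
ds
#> <synthetic_dataset> 500 genes x 120 samples; 73 complex subunits (61 attenuated);
#>   0 regulatory edges; 10.0% protein entries missing

att <- gene_attenuation(ds$cnv, ds$mrna, ds$protein, seed = 1)
dplyr::arrange(att, dplyr::desc(score))[1:5, c(1:3, 6:8)]
#> # A tibble: 5 × 6
#>   entity r_cnv_mrna r_cnv_protein score gmm_class  gmm_posterior
#> 1 g0479       0.871        0.0181 0.853 attenuated             1
#> 2 g0024       0.814       -0.0134 0.828 attenuated             1
#> 3 g0292       0.887        0.0679 0.819 attenuated             1
#> 4 g0197       0.798       -0.0203 0.818 attenuated             1
#> 5 g0434       0.847        0.0329 0.814 attenuated             1

attr(att, "gmm_fit")
#> <gmm_fit> 2 component(s) on 500 scores
#>   means: 0.1036, 0.6489
#>   weights: 0.878, 0.122
```

The top-scoring genes track CNV at the transcript (r ≈ 0.8–0.9) but not the
protein (r ≈ 0), and the mixture isolates them: 61 of 500 scored genes are
called attenuated, exactly the 61 buffered complex subunits implanted by the
generator (sensitivity and specificity 1.0 at this effect size). `autoplot(att)`
draws the r(CNV, mRNA) vs r(CNV, protein) scatter coloured by class.

The whole analysis runs end-to-end with

```r
run_full_analysis(pipeline_config(simulate = simulation_config(seed = 1),
                                  out_dir = "results_run"))
```

writing attenuation tables, enrichment, co-regulation AROCs, regulatory
associations, the signature and a JSON manifest. A command-line wrapper with
per-stage verbs lives in `inst/scripts/cnvbuffer.R`.

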