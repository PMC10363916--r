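# targetbench

Benchmarking machinery for genetically informed drug-target gene
prioritization.

Human genetics supports drug development when the genes a method
prioritizes for a disease coincide with the genes its drugs target.
`targetbench` implements the full evaluation loop for that question:

* **Gene scoring** from three evidence families:
  * *GWAS*: the gene statistic is the sum of squared SNP z-scores over
    the gene region (±50 kb), whose null distribution is the weighted
    chi-square \(\sum_j \lambda_j\chi^2_{1,j}\) with weights the
    eigenvalues of the local LD matrix (Imhof inversion, saddlepoint
    fallback in the deep tail).
  * *QTL-GWAS Mendelian randomization*: allele harmonization (palindromic
    SNPs and allele-frequency mismatches > 0.05 removed), instrument
    selection (exposure p < 1e-6, LD r² < 0.01), Steiger directionality
    filtering, fixed-effect IVW over Wald ratios
    \(\hat\beta_{MR} = \sum w_i \beta_{out,i}/\beta_{exp,i} / \sum w_i\),
    and lowest-p aggregation across tissues.
  * *Exome*: ingestion and validation of precomputed gene-level burden
    p-values.
* **Network diffusion** by random walk with restart,
  \(p_\infty = (I-(1-r)W)^{-1}p_0\) with \(W\) the column-normalized
  weighted adjacency matrix, including the weighted-degree (r = 0) and
  seeded-random baselines.
* **Drug-target mapping** from indication→drug and drug→target tables
  with confidence (≥ 700) and interaction-type filters, plus exact
  binomial background-enrichment tests and Jaccard overlaps.
* **Evaluation**: Fisher exact odds ratios of top-ranked genes against
  target sets (with the standard OR fallback conventions), DeLong AUCs,
  and between-method concordance across percentile grids.
* **Aggregation** across correlated traits and databases:
  \(\bar b = \frac1m\sum b_i\),
  \(\mathrm{var}(\bar b) = \mathbf 1'SRS\mathbf 1/m^2\) with
  \(R = R_{db} \otimes R_{trait}\), and method-difference z-tests with
  empirical-correlation covariance.
* A **synthetic cohort generator** that plants target enrichment (a
  calibrated odds ratio among top-scored genes), network hub bias for
  target genes, and known MR causal effects — so the entire pipeline is
  validated by parameter recovery, with no external downloads.

See the methods vignette (`vignettes/targetbench-methods.Rmd`) for the
models, numerical choices and generator assumptions.

## Worked example

```r
library(targetbench)

cfg <- run_config(
  synthetic_config(n_genes = 20000, n_traits = 10, n_databases = 2,
                   testable_fractions = c(GWAS = 1),
                   target_enrichment_or = 3, hub_bias = 1,
                   top_fraction = c(GWAS = 0.01), seed = 7),
  methods = "GWAS", r_grid = c(0.4, 1), top_fraction = c(GWAS = 0.01))
run <- run_benchmark(cfg)
print(run)
#> benchmark_run: 80 observation(s), methods GWAS, degree, random, r in {0, 0.4, 1}
#>  method   r overall_or or_ci_lo or_ci_hi overall_auc
#>    GWAS 0.4       3.47     3.03     3.96       0.615
#>    GWAS 1.0       3.30     2.88     3.79       0.575
#>  degree 0.0       2.87     2.48     3.32       0.582
#>  random 0.4       3.00     2.60     3.46       0.572
```

Reading the output: the undiffused GWAS scores (r = 1) recover the
planted top-1% enrichment — the overall OR is 3.30 with a 95% CI
covering the planted 3. Diffusing them over the hub-biased network at
r = 0.4 raises both OR and AUC. The two genetics-free baselines expose
the hub circularity the AUC ranking is sensitive to: because targets
were planted as hubs, both the pure degree ranking (r = 0) and diffused
random scores also reach target-enriched ORs near 3, yet genetics still
wins on AUC (0.615 vs 0.582 and 0.572).

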