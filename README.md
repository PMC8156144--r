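# sigscore

Derivation and validation of small fold-change-weighted gene expression
signatures, built around the workflow used to develop pretreatment
predictors of pathological complete response (pCR) to neoadjuvant
chemotherapy in triple-negative breast cancer.

## The problem and the method

Fewer than half of TNBC patients achieve pCR after neoadjuvant chemotherapy,
so a compact pretreatment biomarker of response has direct clinical value.
Because cytotoxic chemotherapy acts on proliferating cells, the screen is
restricted to a cell-cycle pathway gene set (e.g. the 200-gene E2F-target
program) rather than the whole transcriptome. Within that set, responders
and non-responders are compared with an empirical-Bayes **moderated t-test**
(pooled variances shrunk toward a method-of-moments scaled-F prior) and
Benjamini–Hochberg adjustment. The top *k* genes (default 3) among those
with adjusted *p* < 0.05 form the signature, each weighted by its training
log2 fold change:

    score_s = Σ_g  log2FĈ_g · x_gs        (x = log2 expression)

Each cohort is then dichotomized at its own top tertile
(`round(n/3)` samples = "high"), and the frozen-weight score is validated
with ROC-AUC, a paired DeLong comparison against a whole-pathway
single-sample enrichment score, a per-gene AUC scan, a high-vs-low pCR-rate
Fisher exact test, and treatment-stratified Kaplan–Meier / log-rank
survival (OS/DFS/DSS). A synthetic cohort generator with planted
response-associated genes and arm-specific survival hazards makes the whole
pipeline runnable and testable with no external data.

## Worked example

```r
library(sigscore)

train <- simulate_cohort(cohort_config(de_log2fc = c(1.6, 1.2, 1.0), seed = 7))
deriv <- run_derivation(train$expression, train$clinical,
                        train$gene_sets, "SIM_PATHWAY")
deriv$model
#> Signature model 'fc_weighted_signature' (3 genes)
#> GENE0001 GENE0002 GENE0003
#> 1.482494 1.070231 1.045794
c(auc = deriv$roc$auc, auc_pathway = deriv$roc_pathway$auc,
  delong_p = deriv$delong$p)
#>          auc  auc_pathway     delong_p
#> 9.528302e-01 5.841686e-01 3.594312e-14
sum(deriv$scores$group == "high")
#> [1] 57

val <- simulate_cohort(cohort_config(n_samples = 200,
                                     de_log2fc = c(1.6, 1.2, 1.0), seed = 8))
v <- run_validation(val$expression, val$clinical, deriv$model)
c(auc = v$roc$auc, fisher_p = v$fisher$p)
#>          auc     fisher_p
#> 9.577208e-01 1.382211e-30
round(sapply(v$survival, function(f) f$log_rank$p), 4)
#>                   OS   OS.chemotherapy=no  OS.chemotherapy=yes
#>               0.1944               0.6652               0.0363
#>                  DFS  DFS.chemotherapy=no DFS.chemotherapy=yes
#>               0.0519               0.6260               0.0264
#>                  DSS  DSS.chemotherapy=no DSS.chemotherapy=yes
#>               0.0040               0.5137               0.0027
```

The derivation recovered the three planted genes with weights close to the
planted effects, the composite score discriminates responders far better
than the diffuse 200-gene pathway score (DeLong p ≪ 0.01), exactly 57 of
170 samples land in the high-score tertile, and on the independent
validation cohort the frozen weights still separate responders — with the
survival benefit of a high score confined to the chemotherapy-treated arm,
the predictive (rather than prognostic) pattern the design encodes.

Each analysis step is also exposed directly: `moderated_t_test()`,
`select_signature()`, `compute_score()`, `dichotomize_top_fraction()`,
`pathway_ssgsea_score()`, `roc_auc()`, `delong_compare()`,
`per_gene_auc_scan()`, `fisher_exact_2x2()`, `mann_whitney_u()`,
`kruskal_wallis()`, `spearman_rho()`, `kaplan_meier()`, `log_rank()`,
`stratified_survival_analysis()`, plus TSV/CSV/GMT/YAML readers and writers
(`read_expression_matrix()`, `read_gmt()`, `read_clinical()`, ...) and a
file-driven `run_pipeline(config.yaml)`.

See `vignettes/signature-derivation.Rmd` for the model, conventions,
generator assumptions, and power analysis of the default planted effects.

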