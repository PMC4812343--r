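# yeastpgx

Predicting human pharmacogenomic (PGx) associations from yeast
chemogenomic screens.

A PGx association links a drug to a gene whose variation affects
individual response to that drug. Curated human PGx knowledge covers only
a few thousand pairs, but genome-scale chemogenomic screens in
*S. cerevisiae* have measured the fitness of thousands of gene-deletion
strains — HIP (haploinsufficiency, heterozygous deletions of essential
genes) and HOP (homozygote, non-essential genes) profiles — under
hundreds of compounds. `yeastpgx` projects that evidence across species
and is aimed at computational biologists triaging candidate drug–gene
pairs for follow-up.

## The method

A candidate association between drug *D* and human gene *G* is scored
against a chemogenomic screen by the **maximal geometric mean**

```
F(D, G) = max over screened (d, g) of
          ( drugSim(D, d) · geneSim(G, g) · CGI(d, g) )^(1/3)
```

where `drugSim` is chemical-fingerprint Tanimoto or ATC-hierarchy
similarity, `geneSim` is yeast-protein alignment coverage (E < 0.01) or
cross-species domain Jaccard, and `CGI(d, g) ∈ [0, 1]` is the normalized
chemogenomic response of deletion strain *g* to drug *d*. Any zero factor
kills a triple, so non-responding strains and dissimilar drugs or genes
contribute nothing. Two drug measures × two gene measures × two assays
give 8 features per screen source (24 over three sources); a seeded
probability Random Forest turns them into an association probability.
The package also provides negative-pair samplers (uniform and
conservation-matched in 50 homology-coverage bins), repeated stratified
cross-validation with class-imbalance sweeps, external association-matrix
ROC validation, hypergeometric enrichment with BH q-values, two
comparison baselines (PPI-neighbour and human-only known-association
similarity) with a valid-set head-to-head protocol, and a synthetic-corpus
generator with planted signal so everything runs offline.

See `vignette("projection-method")` for the model, its assumptions, and
the design choices.

## Worked example

```r
library(yeastpgx)

# a synthetic corpus with planted associations (three HIP/HOP screens)
corpus <- generate_corpus(simulation_config(
  n_drugs = 100, n_human_genes = 250, n_yeast_genes = 150,
  n_positives = 120, seed = 7
))
corpus
#> <pgx_corpus> 100 drugs, 250 human genes, 150 yeast genes, 120 positives, 6 screens

sims <- corpus_similarities(corpus)
sims$gene$sequence
#> <pgx_sim> sequence: 250 x 150, 225 stored entries

# score one planted pair against one screen: the best screened (drug,
# strain) triple supporting it has geometric mean 0.77
p <- corpus$gold$pairs[1, ]
feature_score(p$drug_id, p$gene_id,
              sims$drug$chemical, sims$gene$sequence,
              corpus$cgi[["screen_a_HIP"]])
#> [1] 0.7714708

# 24-feature matrix over the full candidate grid, then 10 runs of
# stratified 10-fold cross-validation with fresh balanced negatives
pairs <- tidyr::expand_grid(drug_id = corpus$drugs$drug_id,
                            gene_id = corpus$human_genes$gene_id)
features <- build_feature_matrix(pairs, sims$drug, sims$gene, corpus$cgi)
#> feature matrix: 25000 pairs x 24 feature columns

cv <- cross_validate(features, corpus$gold$pairs,
                     neg_ratio = 1, n_runs = 10, k = 10, seed = 17)
glance(cv)
#> # A tibble: 1 × 7
#>   n_runs neg_ratio n_positives auc_mean auc_sd aupr_mean aupr_sd
#>    <int>     <dbl>       <int>    <dbl>  <dbl>     <dbl>   <dbl>
#> 1     10         1         120    0.964 0.0128     0.940  0.0265
```

The planted signal is recovered (mean AUC 0.96). Destroying the
drug–gene linkage of the screens — permuting strain labels with
`shuffle_cgi_null()` while preserving every marginal — collapses the same
cross-validation to chance:

```r
cv_null <- cross_validate(
  build_feature_matrix(pairs, sims$drug, sims$gene,
                       shuffle_cgi_null(corpus, 1)$cgi),
  corpus$gold$pairs, neg_ratio = 1, n_runs = 10, k = 10, seed = 17)
glance(cv_null)$auc_mean
#> [1] 0.528
```

`autoplot(cv)` shows the per-run metrics, `plot_negative_sweep()` the
imbalance sweep, and `tidy()`/`glance()` work on fitted forests and CV
reports. A thin CLI over the same functions is installed at
`inst/scripts/yeastpgx` (`simulate`, `build-features`, `train-predict`,
`evaluate-cv`).

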