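---
title: "Projecting yeast chemogenomic profiles onto human pharmacogenomic associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting yeast chemogenomic profiles onto human pharmacogenomic associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A pharmacogenomic (PGx) association links a drug to a gene whose variation
influences individual response to that drug — metabolizing enzymes,
transporters, targets, or genes acting far downstream. Curated human PGx
knowledge is sparse: a few thousand associations against tens of millions
of candidate drug–gene pairs. In *Saccharomyces cerevisiae*, by contrast,
genome-scale chemogenomic screens have measured the fitness of thousands of
gene-deletion strains under hundreds of compounds. A HIP (haploinsufficiency)
profile scores heterozygous deletions, covering essential genes; a HOP
(homozygote) profile scores homozygous deletions of non-essential genes. A
strong fitness effect of deleting yeast gene *g* under drug *d* is direct,
unbiased evidence that *g* modulates the cellular response to *d*.

`yeastpgx` projects that evidence across species. A candidate association
between drug $D$ and human gene $G$ is scored against a chemogenomic screen
by

$$
F(D, G) \;=\; \max_{d,\,g}\;
\bigl(\, \mathrm{drugSim}(D, d)\cdot \mathrm{geneSim}(G, g)\cdot
\mathrm{CGI}(d, g) \,\bigr)^{1/3},
$$

where $d$ ranges over screened drugs, $g$ over yeast deletion strains,
and $\mathrm{CGI}(d,g) \in [0,1]$ is the normalized chemogenomic response.
The geometric mean gives the three factors equal weight; the maximum keeps
only the best-supported screened pair, so strains that did not respond
(CGI = 0) and dissimilar drugs or genes contribute nothing. With two drug
similarity measures × two gene similarity measures × two assays, each
screen source yields 8 features; three sources yield 24. A probability
Random Forest combines them, and its mean-over-trees class probability is
the association score. Pairs scored at tree unanimity (probability 1) form
the high-confidence prediction set.

## The four similarity measures

All measures live in $[0,1]$ and are stored sparsely (an absent entry is 0);
matrix builders keep *every* positive-scoring pair (a many-to-many map), so
all homologs and all similar drugs can carry evidence, not only best hits.

* **Chemical (Tanimoto)** — intersection over union of hashed
  path-fingerprint bits. For SMILES input the package computes Open Babel
  FP2 fingerprints via ChemmineR (hashed linear substructures of length
  1–7, 1024 bits), the classic "daylight-like" family. Two empty
  fingerprints score 0, not 1: no shared chemistry is no evidence.
* **ATC hierarchy** — drugs are compared over the top three levels of the
  WHO Anatomical Therapeutic Chemical classification (anatomical group,
  1 character; therapeutic subgroup, 3; pharmacological subgroup, 4).
  For each pair of codes the deepest shared level $L \in \{0,1,2,3\}$ is
  found and the score is $\max L/3$ over all code pairs, so it takes
  exactly the values $\{0, \tfrac13, \tfrac23, 1\}$. The denominator 3
  is the package's normalization choice (three levels compared, perfect
  agreement = 1). Codes shorter than a level's width simply contribute no
  prefix at that level.
* **Sequence (alignment coverage)** — the fraction of the *yeast* protein
  covered by an alignment to the human protein, keeping only significant
  alignments (E-value < 0.01) and the largest aligned portion among
  multiple alignments. The measure is deliberately asymmetric (yeast
  coverage); rows of the gene matrix are human genes, columns yeast genes.
* **Domain (Jaccard)** — Jaccard index of protein-domain sets after
  restricting both to the domains observed in at least one protein of
  *each* species; this filter removes lineage-specific domains that could
  never carry cross-species evidence.

For the human-only baseline, human–human gene similarity is needed. Domain
similarity drops the cross-species filter (both sides are human). Directed
alignment coverage is symmetrized by taking the maximum of the two
directions — the directionalization is not forced by anything, and the
maximum keeps the measure consistent with the "best evidence" convention
used everywhere else. The diagonal is fixed at 1: a gene is fully similar
to itself.

## Chemogenomic preparation

Screens arrive as per-condition score tables with condition metadata
(drug, concentration, assay, source). Preparation is:

1. conditions not mapped to a ground-set drug are dropped;
2. per (source, assay, drug), the highest-concentration condition
   represents the drug (ties broken by smallest condition id; drugs with
   no parsable concentration keep their first condition, with a warning);
3. scores are normalized to $[0,1]$ by dividing absolute values by the
   maximal absolute score of the whole per-source, per-assay dataset.
   Taking absolute values treats sensitivity and resistance alike —
   direction is not retained. Normalization is idempotent and
   scale-invariant, so the heterogeneous raw units of different screens
   (log-ratios, MADL, FD-scores) need no special handling.

Normalization happens after condition selection; `prepare_cgi()` keeps the
two steps separate so the other order can be composed manually if wanted.
Missing cells are treated as score 0, not NA — the feature maximum ignores
zeros naturally.

The robustness filter `drop_high_load_drugs()` removes the
$\lceil 0.05\,n \rceil$ drugs with the highest total normalized response.
The ceiling is deliberate: it reproduces removal counts of 1, 2, 3 and 6
for screens of 18, 22, 60 and 111 drugs, whereas floor or rounding do not.

## Classifier and negative sampling

True associations are vastly outnumbered by unlabeled pairs, so negatives
are *sampled* from the non-positive candidate grid. Two samplers are
provided: uniform, and conservation-matched — genes are binned into 50
equal-width bins of best-homolog alignment coverage and negative genes are
drawn with the positive set's bin frequencies, which controls for the
worry that the classifier merely detects "has a conserved yeast homolog".

The forest is a probability forest (ranger): each tree reports the class
frequency of the leaf a pair lands in, and the prediction is the mean over
trees. Forest size is pinned at 100 trees, `min.node.size = 1` (fully
grown trees, so a tree's leaf is near-pure and the mean over trees behaves
like a vote fraction), `mtry` at its default $\lfloor\sqrt{24}\rfloor = 4$,
seeded and single-threaded: retraining with the same seed, data, and
column order reproduces probabilities exactly. The "strict cutoff 1" used
for calling high-confidence predictions means tree unanimity and is
absorbed for floating point as $1 - 1/(2\cdot\texttt{num\_trees})$.

Evaluation is 10 independent runs of stratified 10-fold cross-validation;
each run draws a fresh negative set (seeds `seed + 0 … seed + 9`), and
held-out predictions are pooled within a run into one AUC/AUPR (the
per-fold mean AUC is reported alongside, since either pooling convention
is defensible). AUC uses the Mann–Whitney tie convention (ties count 1/2);
AUPR integrates the precision–recall points by trapezoid. External
validation builds binary association matrices (targets, enzymes,
transporters, or pathway cross products) restricted to the ground set,
discards categories spanning fewer than 5 ground-set drugs, and computes
the ROC of predicted probabilities over the matrix's full drug × gene
space with unscored pairs at probability 0 — absence of evidence is the
model's genuine output, not missing data.

## Baselines and the head-to-head protocol

Two comparison predictors are included. The **PPI-neighbour** method
scores (D, G) by four features: the maximal chemical or ATC similarity
between D and any drug associated (by known PGx, or by drug–target links)
with an immediate network neighbour of G; the maximum is used as the
aggregator, consistent with the main method. The **human-only** method
replaces the chemogenomic factor entirely: its features are the maximal
geometric mean $\sqrt{\mathrm{drugSim}(D,d)\cdot\mathrm{geneSim}(G,g)}$
over known human associations $(d,g)$, with the query pair excluded from
its own evidence.

The head-to-head protocol compares two methods on the intersection of
their *valid* gold-standard sets — the pairs for which each method can
compute features. Each method trains on its valid set minus the
intersection (plus equal random negatives) and both are tested on the
intersection (plus an equal shared negative set drawn from the gene space
both can score). Validity is where a design choice was genuinely open: the
PPI method requires the gene to have a reported interaction; for the
human-only method the package requires the query drug and gene to have
positive similarity to at least one *revealed* known association —
otherwise every feature is structurally zero and "feature calculation" is
vacuous. Taking the looser reading (any annotated pair is valid) makes the
human-only valid set a superset of the yeast method's and leaves the yeast
method nothing to train on — the protocol's own degenerate error case.

## The synthetic corpus

`generate_corpus()` emulates the structural assumptions the method
exploits, with a planted signal, so the whole pipeline is testable with no
external data. Defaults are the study conditions used by the package's
own acceptance checks: 200 drugs × 500 human genes × 300 yeast genes,
200 planted positives, 3 screen sources, signal strength $s = 0.9$, noise
SD $\sigma = 0.1$.

* **Drugs** fall into 40 chemical clusters. Cluster members share a core
  of fingerprint bits (40 core bits kept with probability 0.8, plus 15
  noise bits in a 512-bit space) and, with probability $s$, the cluster's
  ATC code prefix; the toy ATC hierarchy has 5 × 4 × 3 branches, small
  enough that the level similarity takes all four values with useful
  frequency.
* **Genes**: 90% of human genes get a yeast homolog, with alignment
  coverage drawn from Beta(5, 2) (right-skewed, mean ≈ 0.71 — most
  homologs align well, a tail aligns poorly) and mostly inherited domains;
  decoy alignments with E ≥ 0.01 exercise the significance filter. Human
  paralogs (genes sharing a yeast partner) receive human–human alignments
  for the baseline's sequence measure.
* **Screens**: each source screens 60 drugs chosen to cover the clusters;
  every cell gets background noise $N(0, \sigma)$, and for each planted
  positive (D, G) whose gene has a homolog, the screened cluster-mate of D
  and the homolog of G receive $N(s, \sigma)$ in both assays. Some drugs
  are screened at two concentrations with attenuated scores at the lower
  one, exercising highest-concentration selection.
* **Positives are uniform over the drug × gene grid.** Signal is planted
  only when the gene has a homolog. This matters: if positives were drawn
  among homologous genes only, "gene has a yeast homolog" would separate
  classes even after destroying the screens, and the shuffled null below
  could not sit at AUC 0.5. The cost is a ~10% ceiling loss in recoverable
  signal, which the planted-signal check absorbs.
* **PPI network**: 70% of genes are in the network (so validity genuinely
  restricts the PPI baseline); genes sharing a planted drug are
  preferentially connected, plus background edges at mean degree 4.
  Drug–target links are a 30% sample of the positives plus random noise
  pairs.

Each artifact draws from its own RNG stream derived from the master seed,
so changing one component's parameters leaves the others byte-identical.
`shuffle_cgi_null()` permutes the yeast-gene labels of each prepared
screen independently — marginals survive, drug–gene linkage dies — giving
the negative control: cross-validated AUC collapses to ≈ 0.5.

What the generator does *not* emulate: the real screens' score
distributions (log-ratio vs MADL vs FD shapes), essentiality structure
(HIP and HOP cover the same strain set here), correlated assay noise, and
the long-tailed promiscuity of real drugs. Passing tests therefore show
that the pipeline recovers a planted cross-species signal under realistic
sparsity and confounding — not that real screens carry such signal; that
is the published result the method rests on.

## Numerical choices and degenerate inputs

* Empty-vs-empty fingerprints score 0; all-zero chemogenomic datasets
  normalize to all-zero (no division); a feature with no positive triple
  is 0, with a warning when the query is entirely outside the similarity
  row spaces.
* Geometric means are computed as the cube (square) root of the product —
  no epsilon smoothing; a zero factor annihilates the triple by design.
* Concentration ties break by smallest condition id; load-filter ties by
  load then drug id; identical rules make runs reproducible.
* Single-class training labels, degenerate truth matrices (all 0/1),
  cutoffs outside $[0,1]$, and fractions outside $(0,1)$ are errors, not
  silent defaults.
* Benjamini–Hochberg q-values accompany batches of hypergeometric
  enrichment tests.

## Problem sizes used by the self-tests

The package's test-suite and acceptance script run entirely on the
synthetic corpus at the default scale above: cross-validation uses
10 runs × 10 folds at negative ratios 1–50 (up to 10,200 pairs per run),
the baseline comparison averages 10 reseeded head-to-head rounds with 10%
of positives revealed to the knowledge-based baselines, and the oracle
checks use up to 20 × 20 × 400 exhaustive instances. These sizes were
chosen to make the statistical behaviour (AUC stability under imbalance,
AUPR decay, null collapse) clearly visible while staying comfortable on a
single CPU.

## Known limitations

* The feature score transfers evidence only through similarity to
  *screened* drugs and *conserved* genes; drugs unlike anything screened
  in yeast, and genes without yeast homology, score 0 everywhere and are
  invisible to the method.
* ATC similarity saturates at the pharmacological subgroup (level 3);
  finer chemical subgroups are intentionally ignored, as chemical
  similarity is measured separately by fingerprints.
* The human-only baseline's validity definition (above) is the package's
  reading of "feature calculation is feasible"; under the looser reading
  the head-to-head protocol is undefined for that comparison.
* Scores are treated as exchangeable across screens after normalization;
  no cross-screen batch correction is attempted beyond the per-dataset
  maximum scaling.
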