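# Independent brute-force oracles the implementation is checked against.

# exhaustive triple loop over every screened (drug, yeast gene) cell
oracle_feature_score <- function(drug_id, gene_id, drug_sim, gene_sim, cgi) {
  dmat <- as.matrix(drug_sim$mat)
  gmat <- as.matrix(gene_sim$mat)
  best <- 0
  for (r in seq_len(nrow(cgi$scores))) {
    d <- cgi$scores$drug_id[r]
    g <- cgi$scores$yeast_gene_id[r]
    ds <- if (drug_id %in% rownames(dmat) && d %in% colnames(dmat)) dmat[drug_id, d] else 0
    gs <- if (gene_id %in% rownames(gmat) && g %in% colnames(gmat)) gmat[gene_id, g] else 0
    best <- max(best, ds * gs * cgi$scores$score[r])
  }
  best^(1 / 3)
}

# set similarity via logical membership vectors over an explicit universe
oracle_set_ratio <- function(a, b, universe) {
  ina <- universe %in% a
  inb <- universe %in% b
  if (!any(ina | inb)) return(0)
  sum(ina & inb) / sum(ina | inb)
}

# upper hypergeometric tail by direct summation of choose() terms
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# PPI-neighbour features by direct enumeration
oracle_hansen <- function(drug_id, gene_id, edges, pgx, targets, sims) {
  nb <- unique(c(
    edges$gene_b[edges$gene_a == gene_id],
    edges$gene_a[edges$gene_b == gene_id]
  ))
  out <- c()
  for (dm in c("chemical", "atc")) {
    m <- as.matrix(sims[[dm]]$mat)
    for (assoc in list(pgx = pgx, target = targets)) {
      ds <- unique(assoc$drug_id[assoc$gene_id %in% nb])
      ds <- intersect(ds, colnames(m))
      out <- c(out, if (length(ds)) max(m[drug_id, ds]) else 0)
    }
  }
  out
}
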