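# Shared fixtures, built in code. The small corpus keeps module tests
# fast; the acceptance corpus (200 x 500 x 300, 200 positives) lives in
# test-acceptance.R.

small_config <- function(seed = 42, ...) {
  simulation_config(
    n_drugs = 60, n_human_genes = 120, n_yeast_genes = 80, n_positives = 50,
    n_clusters = 15, n_screened = 20, seed = seed, ...
  )
}

small_corpus_cache <- new.env(parent = emptyenv())

small_corpus <- function() {
  if (is.null(small_corpus_cache$corpus)) {
    small_corpus_cache$corpus <- generate_corpus(small_config())
    small_corpus_cache$sims <- corpus_similarities(small_corpus_cache$corpus)
  }
  small_corpus_cache$corpus
}

small_sims <- function() {
  small_corpus()
  small_corpus_cache$sims
}

# toy similarity matrix from a dense matrix with ids
toy_sim <- function(m, rows, cols, measure = "toy") {
  dimnames(m) <- list(rows, cols)
  new_pgx_sim(m, measure)
}

# chemogenomic dataset with already-normalized scores, for hand-built cases
toy_cgi <- function(genes, drugs, scores, source = "toy", assay = "HIP") {
  ds <- new_pgx_cgi(source, assay, tibble::tibble(
    yeast_gene_id = genes, drug_id = drugs, raw_score = scores
  ))
  ds$scores$score <- scores
  ds$normalized <- TRUE
  ds
}
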