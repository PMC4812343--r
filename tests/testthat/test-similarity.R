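test_that("Tanimoto handles identity, disjoint, and mixed bit sets", {
  expect_equal(tanimoto(c(5, 9, 13), c(5, 9, 13)), 1)
  expect_equal(tanimoto(1:3, 4:6), 0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(integer(0), integer(0)), 0) # no shared evidence
  expect_equal(tanimoto(c(1, 2), c(2, 1)), 1) # order-free
})

test_that("Tanimoto and domain Jaccard match a set-enumeration oracle", {
  universe <- 1:64
  withr::with_seed(3, {
    for (i in 1:300) {
      a <- sample(universe, sample(0:12, 1))
      b <- sample(universe, sample(0:12, 1))
      expect_equal(tanimoto(a, b), oracle_set_ratio(a, b, universe))
      expect_equal(
        domain_similarity(as.character(a), as.character(b),
                          as.character(universe)),
        oracle_set_ratio(as.character(a), as.character(b), as.character(universe))
      )
    }
  })
})

test_that("ATC similarity scores the deepest shared hierarchy level", {
  expect_equal(atc_similarity("N06AB03", "N06AB03"), 1)
  expect_equal(atc_similarity("N06AB03", "N05AH02"), 1 / 3)
  expect_equal(atc_similarity("A01AB", "N06AB"), 0)
  expect_equal(atc_similarity("N06AB03", "N06CA02"), 2 / 3)
  expect_equal(atc_similarity("N06AB03", "N06AH02"), 1) # shared pharmacological level
  # max over code pairs; shorter prefixes tolerated
  expect_equal(atc_similarity(c("A01AB", "N06"), c("N06AB03")), 2 / 3)
  expect_equal(atc_similarity("N", "N06AB03"), 1 / 3)
  expect_error(atc_similarity(character(0), "N06AB03"))
  # symmetry
  expect_equal(atc_similarity("N06AB03", "N05AH02"),
               atc_similarity("N05AH02", "N06AB03"))
})

test_that("ATC similarity takes exactly the values {0, 1/3, 2/3, 1} on the toy hierarchy", {
  corpus <- small_corpus()
  sim <- small_sims()$drug$atc
  vals <- unique(as.numeric(as.matrix(sim$mat)))
  expect_true(all(vapply(
    vals, function(v) any(abs(v - c(0, 1 / 3, 2 / 3, 1)) < 1e-12), logical(1)
  )))
  expect_setequal(round(vals, 10), round(c(0, 1 / 3, 2 / 3, 1), 10))
})

test_that("sequence similarity applies the E-value filter and max-span rule", {
  rec <- function(span, e) tibble::tibble(aligned_span = span, e_value = e)
  expect_equal(sequence_similarity(rec(200, 1e-50), 200), 1)
  expect_equal(sequence_similarity(rec(c(50, 80), c(1e-5, 1e-9)), 200), 0.4)
  expect_equal(sequence_similarity(rec(150, 0.05), 200), 0)
  expect_equal(sequence_similarity(rec(integer(0), numeric(0)), 200), 0)
  expect_error(sequence_similarity(rec(300, 1e-5), 200), "corrupt")
})

test_that("sequence similarity is monotone in span and ignores insignificant records", {
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(1:6, 1)
      len <- sample(100:400, 1)
      rec <- tibble::tibble(
        aligned_span = sample(seq_len(len), n, replace = TRUE),
        e_value = 10^runif(n, -30, 1)
      )
      base <- sequence_similarity(rec, len)
      # adding an insignificant record changes nothing
      noisy <- dplyr::bind_rows(rec, tibble::tibble(aligned_span = len, e_value = 0.011))
      expect_equal(sequence_similarity(noisy, len), base)
      # growing any span never decreases the score
      rec2 <- rec
      j <- sample(n, 1)
      rec2$aligned_span[j] <- min(len, rec2$aligned_span[j] + 10)
      expect_gte(sequence_similarity(rec2, len), base)
    }
  })
})

test_that("domain Jaccard filters to the cross-species universe", {
  expect_equal(domain_similarity(c("P1", "P2"), c("P1", "P2"), c("P1", "P2")), 1)
  expect_equal(domain_similarity(c("P1", "P2"), c("P2", "P3"), paste0("P", 1:3)), 1 / 3)
  # PX is human-only: removed by the universe filter before the Jaccard
  expect_equal(domain_similarity(c("P1", "PX"), "P1", "P1"), 1)
  expect_equal(domain_similarity("PX", "P1", "P1"), 0)
})

test_that("matrix builders agree with the scalar measures and keep all hits", {
  corpus <- small_corpus()
  sims <- small_sims()
  drugs <- corpus$drugs
  withr::with_seed(8, ij <- cbind(sample(nrow(drugs), 25, TRUE), sample(nrow(drugs), 25, TRUE)))
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    expect_equal(
      as.numeric(sims$drug$chemical$mat[drugs$drug_id[i], drugs$drug_id[j]]),
      tanimoto(drugs$fp[[i]], drugs$fp[[j]])
    )
    expect_equal(
      as.numeric(sims$drug$atc$mat[drugs$drug_id[i], drugs$drug_id[j]]),
      atc_similarity(drugs$atc[[i]], drugs$atc[[j]])
    )
  }
  # symmetric with unit diagonal
  expect_true(Matrix::isSymmetric(sims$drug$chemical$mat))
  expect_equal(as.numeric(Matrix::diag(sims$drug$chemical$mat)),
               rep(1, nrow(drugs)))

  # many-to-many: every positive-scoring alignment pair is stored
  aln <- dplyr::filter(corpus$alignments, e_value < 0.01)
  stored <- as_tibble(sims$gene$sequence)
  expect_true(all(
    paste(aln$human_gene_id, aln$yeast_gene_id) %in%
      paste(stored$row_id, stored$col_id)
  ))
  # and matches the scalar on each stored human gene
  one <- stored[which.max(stored$score), ]
  recs <- dplyr::filter(corpus$alignments,
                        human_gene_id == one$row_id, yeast_gene_id == one$col_id)
  ylen <- corpus$yeast_genes$protein_length[
    corpus$yeast_genes$gene_id == one$col_id]
  expect_equal(one$score, sequence_similarity(recs, ylen))
})

test_that("FP2 fingerprints from SMILES feed the Tanimoto measure", {
  skip_if_not_installed("ChemmineR")
  fps <- fingerprint_smiles(c(a = "CCO", b = "CCO", c = "c1ccccc1O"))
  expect_equal(tanimoto(fps$a, fps$b), 1)
  expect_lt(tanimoto(fps$a, fps$c), 1)
  expect_true(all(unlist(fps) <= attr(fps, "nbits")))
})

test_that("human-human similarity symmetrizes coverage and keeps a unit diagonal", {
  genes <- tibble::tibble(
    gene_id = c("h1", "h2", "h3"),
    protein_length = c(100L, 200L, 150L),
    domains = list("P1", "P1", "P2")
  )
  aln <- tibble::tibble(
    query_id = "h1", subject_id = "h2", aligned_span = 80, e_value = 1e-10
  )
  seq_sim <- human_gene_similarity_matrix(genes, aln, "sequence")
  # h1->h2 coverage 0.8 of h1; no reverse record; symmetrized max = 0.8
  expect_equal(as.numeric(seq_sim$mat["h1", "h2"]), 0.8)
  expect_equal(as.numeric(seq_sim$mat["h2", "h1"]), 0.8)
  expect_equal(as.numeric(Matrix::diag(seq_sim$mat)), rep(1, 3))
  dom_sim <- human_gene_similarity_matrix(genes, measure = "domain")
  expect_equal(as.numeric(dom_sim$mat["h1", "h2"]), 1)
  expect_equal(as.numeric(dom_sim$mat["h1", "h3"]), 0)
})
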