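# Hand-built two-drug, two-gene instance used across several cases:
# drugSim(D, .) = (0.8, 0.2), geneSim(G, .) = (0.5, 1.0),
# CGI = d1:(g1 0.9, g2 0.1), d2:(g1 0.3, g2 0.6)
toy_instance <- function() {
  list(
    drug_sim = toy_sim(matrix(c(1, 0.8, 0.2, 0.8, 1, 0, 0.2, 0, 1), 3, 3),
                       c("D", "d1", "d2"), c("D", "d1", "d2"), "chemical"),
    gene_sim = toy_sim(matrix(c(0.5, 1.0), 1, 2), "G", c("g1", "g2"), "sequence"),
    cgi = toy_cgi(c("g1", "g2", "g1", "g2"), c("d1", "d1", "d2", "d2"),
                  c(0.9, 0.1, 0.3, 0.6))
  )
}

test_that("the feature score is the maximal geometric mean over the screen grid", {
  inst <- toy_instance()
  # products: 0.8*0.5*0.9, 0.8*1*0.1, 0.2*0.5*0.3, 0.2*1*0.6 -> max 0.36
  expect_equal(
    feature_score("D", "G", inst$drug_sim, inst$gene_sim, inst$cgi),
    0.36^(1 / 3)
  )
  # a perfect triple scores 1
  perfect <- toy_cgi("g2", "d1", 1)
  ds <- toy_sim(matrix(1, 1, 1), "D", "d1", "chemical")
  gs <- toy_sim(matrix(1, 1, 1), "G", "g2", "sequence")
  expect_equal(feature_score("D", "G", ds, gs, perfect), 1)
  # all-zero CGI kills every product
  dead <- toy_cgi(c("g1", "g2"), c("d1", "d1"), c(0, 0))
  expect_equal(feature_score("D", "G", inst$drug_sim, inst$gene_sim, dead), 0)
  # query outside the similarity row space: warning and 0
  expect_warning(
    s <- feature_score("Dx", "G", inst$drug_sim, inst$gene_sim, inst$cgi),
    "no similarity evidence"
  )
  expect_equal(s, 0)
})

test_that("feature_score equals the exhaustive triple-loop oracle", {
  withr::with_seed(21, {
    for (i in 1:40) {
      nd <- sample(3:10, 1); ng <- sample(3:10, 1); nq <- sample(2:6, 1)
      drugs <- sprintf("d%d", seq_len(nd)); genes <- sprintf("g%d", seq_len(ng))
      queries_d <- sprintf("QD%d", seq_len(nq)); queries_g <- sprintf("QG%d", seq_len(nq))
      dmat <- matrix(round(runif(nq * nd), 3) * rbinom(nq * nd, 1, 0.6), nq, nd)
      gmat <- matrix(round(runif(nq * ng), 3) * rbinom(nq * ng, 1, 0.6), nq, ng)
      ds <- toy_sim(dmat, queries_d, drugs, "chemical")
      gs <- toy_sim(gmat, queries_g, genes, "sequence")
      cells <- sample(nd * ng, sample(5:(nd * ng), 1))
      cgi <- toy_cgi(
        genes[(cells - 1) %% ng + 1], drugs[(cells - 1) %/% ng + 1],
        round(runif(length(cells)), 3)
      )
      for (q in seq_len(nq)) {
        expect_equal(
          feature_score(queries_d[q], queries_g[q], ds, gs, cgi),
          oracle_feature_score(queries_d[q], queries_g[q], ds, gs, cgi)
        )
      }
    }
  })
})

test_that("feature_score is monotone, bounded by the max factor, and zero-CGI-invariant", {
  inst <- toy_instance()
  base <- feature_score("D", "G", inst$drug_sim, inst$gene_sim, inst$cgi)
  # raising any CGI entry never decreases the score
  up <- inst$cgi
  up$scores$score[3] <- 0.9
  expect_gte(feature_score("D", "G", inst$drug_sim, inst$gene_sim, up), base)
  # geometric mean <= max of the factors
  expect_lte(base, max(c(0.8, 0.2, 0.5, 1.0, inst$cgi$scores$score)))
  # cells with CGI = 0 contribute nothing
  padded <- inst$cgi
  padded$scores <- dplyr::bind_rows(
    padded$scores,
    tibble::tibble(yeast_gene_id = "g2", drug_id = "d1", raw_score = 0, score = 0)
  )
  expect_equal(feature_score("D", "G", inst$drug_sim, inst$gene_sim, padded), base)
})

test_that("the feature matrix has 8 columns per screen source in fixed order", {
  corpus <- small_corpus()
  sims <- small_sims()
  pairs <- dplyr::bind_rows(
    corpus$gold$pairs[1:10, ],
    tibble::tibble(drug_id = corpus$drugs$drug_id[1:5],
                   gene_id = corpus$human_genes$gene_id[1:5])
  )
  feats <- suppressMessages(build_feature_matrix(pairs, sims$drug, sims$gene, corpus$cgi))
  expect_equal(ncol(feats) - 2L, 24L)
  expect_equal(names(feats)[-(1:2)], feature_definitions(corpus$cgi)$column)
  expect_true(all(as.matrix(feats[-(1:2)]) >= 0 & as.matrix(feats[-(1:2)]) <= 1))

  # a single source yields 8 columns
  f8 <- suppressMessages(build_feature_matrix(pairs, sims$drug, sims$gene, corpus$cgi[1:2]))
  expect_equal(ncol(f8) - 2L, 8L)

  # permuting the pair order permutes rows, not values
  perm <- withr::with_seed(2, sample(nrow(pairs)))
  feats2 <- suppressMessages(build_feature_matrix(pairs[perm, ], sims$drug, sims$gene, corpus$cgi))
  expect_equal(feats2, feats[perm, ], ignore_attr = TRUE)

  expect_error(build_feature_matrix(pairs[0, ], sims$drug, sims$gene, corpus$cgi),
               "empty")
})

test_that("genes with no yeast similarity under either measure score all-zero rows", {
  corpus <- small_corpus()
  sims <- small_sims()
  reach <- unique(c(
    rownames(sims$gene$sequence$mat)[Matrix::rowSums(sims$gene$sequence$mat) > 0],
    rownames(sims$gene$domain$mat)[Matrix::rowSums(sims$gene$domain$mat) > 0]
  ))
  orphan <- setdiff(corpus$human_genes$gene_id, reach)
  skip_if(length(orphan) == 0, "every synthetic gene has a yeast link at this seed")
  pairs <- tibble::tibble(drug_id = corpus$drugs$drug_id[1], gene_id = orphan[1])
  feats <- suppressMessages(build_feature_matrix(pairs, sims$drug, sims$gene, corpus$cgi))
  expect_equal(unname(unlist(feats[1, -(1:2)])), rep(0, 24))
})

test_that("the human-only baseline is the max geometric mean over known pairs", {
  ds <- toy_sim(matrix(c(0.64, 0.1), 1, 2), "D", c("d1", "d2"), "chemical")
  gs <- toy_sim(matrix(c(0.25, 0.9), 1, 2), "G", c("g1", "g2"), "domain")
  known <- tibble::tibble(drug_id = c("d1", "d2"), gene_id = c("g1", "g2"))
  # max(0.64*0.25, 0.1*0.9) = 0.16 -> sqrt = 0.4
  expect_equal(human_baseline_score("D", "G", known, ds, gs), 0.4)
  expect_equal(human_baseline_score("D", "G", known[0, ], ds, gs), 0)
  # a pair identical to a known association scores 1
  idsim <- toy_sim(diag(2), c("d1", "d2"), c("d1", "d2"), "chemical")
  igsim <- toy_sim(diag(2), c("g1", "g2"), c("g1", "g2"), "domain")
  expect_equal(human_baseline_score("d1", "g1", known, idsim, igsim), 1)
})

test_that("baseline feature building matches the scalar and can exclude self", {
  corpus <- small_corpus()
  sims <- small_sims()
  hsims <- corpus_human_similarities(corpus)
  known <- corpus$gold$pairs[1:15, ]
  pairs <- dplyr::bind_rows(known[1:5, ], corpus$gold$pairs[20:24, ])
  feats <- build_baseline_features(pairs, known, sims$drug, hsims, exclude_self = FALSE)
  expect_equal(ncol(feats) - 2L, 4L)
  for (r in c(1, 6, 9)) {
    expect_equal(
      feats$human_chemical_sequence[r],
      human_baseline_score(pairs$drug_id[r], pairs$gene_id[r], known,
                           sims$drug$chemical, hsims$sequence)
    )
  }
  # with self-exclusion a known pair loses its own (perfect) evidence
  feats_ex <- build_baseline_features(pairs, known, sims$drug, hsims)
  known_self <- known[1, ]
  drop_self <- dplyr::anti_join(known, known_self, by = c("drug_id", "gene_id"))
  expect_equal(
    feats_ex$human_atc_domain[1],
    human_baseline_score(known_self$drug_id, known_self$gene_id, drop_self,
                         sims$drug$atc, hsims$domain)
  )
})
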