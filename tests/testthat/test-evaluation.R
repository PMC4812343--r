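test_that("cross-validation folds partition the pairs within every run", {
  corpus <- small_corpus()
  sims <- small_sims()
  pairs <- tidyr::expand_grid(
    drug_id = corpus$drugs$drug_id, gene_id = corpus$human_genes$gene_id
  )
  feats <- suppressMessages(
    build_feature_matrix(pairs, sims$drug, sims$gene, corpus$cgi)
  )
  cv <- cross_validate(feats, corpus$gold$pairs, neg_ratio = 2, n_runs = 2,
                       k = 5, seed = 17, keep_predictions = TRUE)
  preds <- attr(cv, "predictions")
  pos_keys <- paste(corpus$gold$pairs$drug_id, corpus$gold$pairs$gene_id)
  for (r in unique(preds$run)) {
    sub <- dplyr::filter(preds, run == r)
    sub_pos <- dplyr::filter(sub, label == 1)
    # every positive is scored exactly once, i.e. sits in exactly one fold
    expect_setequal(paste(sub_pos$drug_id, sub_pos$gene_id), pos_keys)
    expect_equal(nrow(sub_pos), length(pos_keys))
    expect_equal(sort(unique(sub$fold)), 1:5)
    # fresh negatives per run at the requested ratio, disjoint from positives
    expect_equal(sum(sub$label == 0), 2 * length(pos_keys))
    expect_false(any(paste(sub$drug_id, sub$gene_id)[sub$label == 0] %in% pos_keys))
  }
  g <- glance(cv)
  expect_equal(g$n_runs, 2)
  expect_true(g$auc_mean >= 0 && g$auc_mean <= 1)
  expect_error(
    cross_validate(feats, corpus$gold$pairs[1:3, ], k = 10),
    "at least k"
  )
})

test_that("AUC follows the Mann-Whitney convention and monotone invariance", {
  labels <- c(1, 0, 1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  expect_equal(auc_score(labels, scores), 6 / 9)
  # ties contribute 1/2
  expect_equal(auc_score(c(1, 0), c(0.5, 0.5)), 0.5)
  withr::with_seed(31, {
    for (i in 1:20) {
      lab <- rbinom(50, 1, 0.4)
      if (all(lab == lab[1])) next
      sc <- runif(50)
      a <- auc_score(lab, sc)
      expect_equal(auc_score(lab, 3 * sc + 2), a)
      expect_equal(auc_score(lab, exp(sc)), a)
      expect_equal(auc_score(lab, rank(sc, ties.method = "average")), a)
    }
  })
})

test_that("AUPR integrates precision-recall by trapezoid", {
  # points: (r=0.5, p=1), (0.5, 0.5), (1, 2/3), (1, 0.5); area = 0.5 + 7/24
  expect_equal(aupr_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.5 + 7 / 24)
  expect_equal(aupr_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6)), 1)
  p <- precision_recall_at(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6), 0.75)
  expect_equal(p$precision, 1)
  expect_equal(p$recall, 1)
  # precision at fixed recall walks the ranked list until recall is reached
  pr <- precision_at_recall(c(1, 0, 1, 0, 1, 0, 0, 0),
                            c(.9, .85, .8, .7, .6, .5, .4, .3), recall = 0.5)
  expect_equal(pr$precision, 2 / 3)
  expect_gte(pr$recall, 0.5)
})

test_that("external matrices expand pathways, dedupe, and drop small categories", {
  drugs <- tibble::tibble(
    drug_id = sprintf("d%d", 1:6), smiles = "CCO", atc_codes = "N06AB03"
  )
  human <- tibble::tibble(gene_id = sprintf("g%d", 1:6), domain_ids = "P1")
  yeast <- tibble::tibble(gene_id = "y1", protein_length = 10L, domain_ids = "P1")
  gs <- suppressMessages(build_ground_set(drugs, human, yeast))

  assoc <- tibble::tibble(
    category = "metabolic",
    pathway_id = c("p1", "p1", "p1", "p2", "p2", rep("p3", 8)),
    drug_id = c("d1", NA, NA, "d1", NA,
                paste0("d", 1:5), NA, NA, NA),
    gene_id = c(NA, "g1", "g2", NA, "g1",
                rep(NA, 5), "g1", "g2", "g3")
  )
  m <- build_external_matrix(assoc, "metabolic", gs, min_drugs = 5)
  # p1: d1 x {g1, g2}; p2 repeats (d1, g1) -> single entry; p3: 5 drugs x 3 genes
  expect_equal(sum(m$pairs$drug_id == "d1" & m$pairs$gene_id == "g1"), 1)
  expect_setequal(m$drugs, paste0("d", 1:5))
  expect_equal(nrow(m$pairs), 15) # d1x{g1,g2} within p3 cross product already

  # a category spanning only 4 ground-set drugs is discarded
  small <- dplyr::mutate(assoc, category = "signaling")[
    assoc$pathway_id == "p3" & (is.na(assoc$drug_id) | assoc$drug_id != "d5"), ]
  expect_message(
    out <- build_external_matrix(small, "signaling", gs, min_drugs = 5),
    "discarded"
  )
  expect_null(out)
  expect_error(build_external_matrix(assoc, "nope", gs), "unknown category")
})

test_that("ROC against an association matrix scores unpredicted pairs as 0", {
  truth <- structure(list(
    pairs = tibble::tibble(drug_id = c("d1", "d2"), gene_id = c("g1", "g2")),
    category = "target", drugs = c("d1", "d2"), genes = c("g1", "g2")
  ), class = "pgx_assoc_matrix")
  perfect <- tidyr::expand_grid(drug_id = c("d1", "d2"), gene_id = c("g1", "g2")) |>
    dplyr::mutate(probability = as.numeric(
      (drug_id == "d1" & gene_id == "g1") | (drug_id == "d2" & gene_id == "g2")
    ))
  expect_equal(roc_against_matrix(perfect, truth), 1)
  inverted <- dplyr::mutate(perfect, probability = 1 - probability)
  expect_equal(roc_against_matrix(inverted, truth), 0)
  # unscored pairs get probability 0
  expect_equal(roc_against_matrix(perfect[perfect$probability > 0, ], truth), 1)

  degen <- truth
  degen$pairs <- tidyr::expand_grid(drug_id = c("d1", "d2"), gene_id = c("g1", "g2"))
  expect_error(roc_against_matrix(perfect, degen), "degenerate")
})

test_that("random predictions give a null AUC against a balanced matrix", {
  withr::with_seed(41, {
    truth <- structure(list(
      pairs = tidyr::expand_grid(
        drug_id = sprintf("d%d", 1:100), gene_id = sprintf("g%d", 1:100)
      )[sample(10000, 5000), ],
      category = "null", drugs = sprintf("d%d", 1:100), genes = sprintf("g%d", 1:100)
    ), class = "pgx_assoc_matrix")
    preds <- tidyr::expand_grid(
      drug_id = sprintf("d%d", 1:100), gene_id = sprintf("g%d", 1:100)
    ) |> dplyr::mutate(probability = runif(10000))
  })
  auc <- roc_against_matrix(preds, truth)
  expect_gt(auc, 0.48)
  expect_lt(auc, 0.52)
})

test_that("prediction-count filtering drops promiscuous drugs", {
  preds <- tibble::tibble(
    drug_id = c(rep("dA", 700), rep("dB", 100)),
    gene_id = sprintf("g%d", 1:800)
  )
  positives <- tibble::tibble(drug_id = c("dA", "dB", "dC"),
                              gene_id = c("g1", "g2", "g3"))
  out <- filter_drugs_by_prediction_count(preds, positives, max_preds = 600)
  expect_setequal(out$drugs, c("dB", "dC"))
  expect_setequal(out$positives$drug_id, c("dB", "dC"))
  # counts equal a brute-force tally
  expect_equal(
    out$counts$n_predictions[match(c("dA", "dB", "dC"), out$counts$drug_id)],
    c(sum(preds$drug_id == "dA"), sum(preds$drug_id == "dB"), 0L)
  )
  all_kept <- filter_drugs_by_prediction_count(preds, positives, max_preds = Inf)
  expect_setequal(all_kept$drugs, c("dA", "dB", "dC"))
  expect_equal(all_kept$positives, positives)
})

test_that("the accumulative hypergeometric test matches exact enumeration", {
  expect_equal(hypergeometric_enrichment(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeometric_enrichment(0, 5, 4, 10), 1)
  expect_equal(hypergeometric_enrichment(10, 10, 10, 10), 1)
  expect_error(hypergeometric_enrichment(5, 4, 4, 10))
  expect_error(hypergeometric_enrichment(2, 11, 4, 10))
  withr::with_seed(51, {
    for (i in 1:100) {
      N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeometric_enrichment(k, K, n, N),
                   oracle_hyper_tail(k, K, n, N))
    }
  })
  batch <- enrich_test(tibble::tibble(
    overlap = c(4, 1), set_size = c(5, 5), sample_size = c(4, 4),
    universe_size = c(10, 10)
  ))
  expect_equal(batch$p_value[1], 5 / 210)
  expect_true(all(batch$q_value >= batch$p_value))
})
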