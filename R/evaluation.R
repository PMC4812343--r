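# Performance evaluation: repeated stratified cross-validation with
# class-imbalance sweeps, external association-matrix ROC validation,
# prediction-count drug filtering, and hypergeometric enrichment.

#' Area under the ROC curve
#'
#' Mann-Whitney convention: ties contribute 1/2. Invariant to strictly
#' monotone transforms of the scores.
#'
#' @param labels 0/1 or logical truth vector.
#' @param scores numeric prediction scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  as.numeric(pROC::auc(
    response = labels, predictor = scores,
    levels = c(0L, 1L), direction = "<", quiet = TRUE
  ))
}

#' Area under the precision-recall curve
#'
#' Precision-recall points at every distinct score threshold (ties
#' grouped), integrated by the trapezoidal rule over recall.
#'
#' @inheritParams auc_score
#' @return AUPR in \[0, 1\].
#' @export
aupr_score <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), any(labels == 1))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  cum_tp <- cumsum(lab)
  cum_fp <- cumsum(1 - lab)
  # keep the last index of each tied-score block
  last <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(lab)
  rec0 <- c(0, rec)
  prec0 <- c(prec[1], prec)
  sum(diff(rec0) * (prec0[-1] + prec0[-length(prec0)]) / 2)
}

#' Precision and recall at a score cutoff
#'
#' @inheritParams auc_score
#' @param cutoff scores at or above the cutoff are called positive.
#' @return Tibble `cutoff`, `precision`, `recall`, `n_called`.
#' @export
precision_recall_at <- function(labels, scores, cutoff) {
  labels <- as.integer(labels)
  called <- scores >= cutoff
  tibble(
    cutoff = cutoff,
    precision = if (any(called)) sum(labels[called]) / sum(called) else NA_real_,
    recall = sum(labels[called]) / sum(labels),
    n_called = sum(called)
  )
}

#' Precision at a fixed recall level
#'
#' Precision at the most permissive cutoff whose recall still reaches the
#' requested level (calls are ranked by score; ties grouped).
#'
#' @inheritParams auc_score
#' @param recall target recall in (0, 1\].
#' @return Tibble `recall_target`, `cutoff`, `precision`, `recall`.
#' @export
precision_at_recall <- function(labels, scores, recall = 0.25) {
  stopifnot(recall > 0, recall <= 1)
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  last <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tp <- cumsum(lab)[last]
  rec <- tp / sum(lab)
  i <- last[which(rec >= recall)[1]]
  tibble(
    recall_target = recall,
    cutoff = sc[i],
    precision = sum(lab[seq_len(i)]) / i,
    recall = sum(lab[seq_len(i)]) / sum(lab)
  )
}

#' Repeated stratified cross-validation with resampled negatives
#'
#' Performs `n_runs` independent runs of `k`-fold cross-validation. Each
#' run draws a fresh negative set of `neg_ratio * n_positives` pairs
#' (seeds `seed + 0 ... seed + n_runs - 1`), splits positives and
#' negatives into `k` stratified folds, trains the forest on k-1 folds and
#' scores the held-out fold, then pools the held-out predictions of the
#' run into one AUC/AUPR (the per-fold mean AUC is reported alongside).
#'
#' @param features feature tibble covering the candidate grid the
#'   negatives are drawn from (`drug_id`, `gene_id`, feature columns).
#' @param positives tibble of positive pairs (at least `k` rows).
#' @param neg_ratio negatives per positive (1 = balanced, up to 50).
#' @param n_runs number of independent runs (default 10).
#' @param k number of folds (default 10).
#' @param seed base seed.
#' @param neg_mode,conservation,n_bins passed to [sample_negatives()].
#' @param num_trees forest size (default 100).
#' @param keep_predictions keep pooled held-out predictions in attribute
#'   `predictions`.
#' @return A `pgx_cv` tibble: one row per run with `auc`, `aupr`,
#'   `auc_foldwise`; summary via [glance()].
#' @export
cross_validate <- function(features, positives, neg_ratio = 1, n_runs = 10, k = 10,
                           seed = 1, neg_mode = "uniform", conservation = NULL,
                           n_bins = 50, num_trees = 100, keep_predictions = FALSE) {
  assert_cols(positives, c("drug_id", "gene_id"), "positive set")
  n_pos <- nrow(positives)
  if (n_pos < k) abort("need at least k positive pairs")
  cols <- setdiff(names(features), c("drug_id", "gene_id"))
  fkeys <- pair_key(features$drug_id, features$gene_id)
  pos_idx <- match(pair_key(positives$drug_id, positives$gene_id), fkeys)
  if (anyNA(pos_idx)) abort("all positives must be present in the feature table")
  n_neg <- neg_ratio * n_pos
  if (n_neg > nrow(features) - n_pos) {
    abort("neg_ratio too large for the available non-positive pairs")
  }

  runs <- map(seq_len(n_runs), function(r) {
    seed_r <- seed + r - 1L
    negs <- sample_negatives(
      positives, features, n_neg,
      mode = neg_mode, seed = seed_r,
      conservation = conservation, n_bins = n_bins
    )
    neg_idx <- match(pair_key(negs$drug_id, negs$gene_id), fkeys)
    if (anyNA(neg_idx)) abort("sampled negatives missing from the feature table")
    idx <- c(pos_idx, neg_idx)
    lab <- rep(c(1L, 0L), c(n_pos, n_neg))
    fold <- withr::with_seed(child_seed(seed_r, 7L), c(
      sample(rep_len(seq_len(k), n_pos)),
      sample(rep_len(seq_len(k), n_neg))
    ))
    pooled_prob <- numeric(length(idx))
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      test <- fold == f
      model <- fit_pgx_forest(features[idx[!test], ], lab[!test],
                              seed = seed_r, num_trees = num_trees)
      pooled_prob[test] <- predict(model, features[idx[test], ])
      fold_auc[f] <- auc_score(lab[test], pooled_prob[test])
    }
    list(
      metrics = tibble(
        run = r, seed = seed_r,
        auc = auc_score(lab, pooled_prob),
        aupr = aupr_score(lab, pooled_prob),
        auc_foldwise = mean(fold_auc)
      ),
      predictions = if (keep_predictions) {
        features[idx, c("drug_id", "gene_id")] |>
          mutate(run = r, label = lab, probability = pooled_prob, fold = fold)
      }
    )
  })

  out <- list_rbind(map(runs, "metrics"))
  attr(out, "neg_ratio") <- neg_ratio
  attr(out, "n_positives") <- n_pos
  attr(out, "k") <- k
  if (keep_predictions) attr(out, "predictions") <- list_rbind(map(runs, "predictions"))
  class(out) <- c("pgx_cv", class(out))
  out
}

#' Summarise a cross-validation report
#'
#' @param x a [cross_validate()] result.
#' @param ... unused.
#' @return One-row tibble with mean and standard deviation of AUC and
#'   AUPR across runs.
#' @export
glance.pgx_cv <- function(x, ...) {
  tibble(
    n_runs = nrow(x),
    neg_ratio = attr(x, "neg_ratio"),
    n_positives = attr(x, "n_positives"),
    auc_mean = mean(x$auc), auc_sd = stats::sd(x$auc),
    aupr_mean = mean(x$aupr), aupr_sd = stats::sd(x$aupr)
  )
}

#' @export
tidy.pgx_cv <- function(x, ...) as_tibble(x)

#' Build a binary external association matrix
#'
#' Turns externally curated drug-gene links (targets, enzymes,
#' transporters) or pathway memberships into a binary association matrix
#' for one category. Pathway rows (carrying a `pathway_id` and either a
#' drug or a gene) expand to the cross product of the pathway's member
#' drugs and genes. Categories spanning fewer than `min_drugs` ground-set
#' drugs are discarded (returns `NULL` with a message).
#'
#' @param associations tibble with `category` plus either direct
#'   `drug_id`, `gene_id` links, or `pathway_id` membership rows with one
#'   of `drug_id`/`gene_id` set per row.
#' @param category the category label to extract.
#' @param ground_set a `pgx_ground_set`.
#' @param min_drugs minimum ground-set drug span (default 5).
#' @return A `pgx_assoc_matrix` (binary pairs plus its drug x gene space),
#'   or `NULL` if discarded.
#' @export
build_external_matrix <- function(associations, category, ground_set, min_drugs = 5) {
  assert_cols(associations, "category", "association table")
  if (!category %in% associations$category) {
    abort(sprintf("unknown category label: %s", category))
  }
  sub <- filter(associations, .data$category == !!category)
  if ("pathway_id" %in% names(associations)) {
    drugs <- sub |> filter(!is.na(.data$drug_id)) |> distinct(.data$pathway_id, .data$drug_id)
    genes <- sub |> filter(!is.na(.data$gene_id)) |> distinct(.data$pathway_id, .data$gene_id)
    pairs <- inner_join(drugs, genes, by = "pathway_id",
                        relationship = "many-to-many") |>
      select("drug_id", "gene_id")
  } else {
    assert_cols(sub, c("drug_id", "gene_id"), "association table")
    pairs <- select(sub, "drug_id", "gene_id")
  }
  pairs <- pairs |>
    filter(
      .data$drug_id %in% ground_set$drugs$drug_id,
      .data$gene_id %in% ground_set$human_genes$gene_id
    ) |>
    distinct(.data$drug_id, .data$gene_id)
  n_drugs <- dplyr::n_distinct(pairs$drug_id)
  if (n_drugs < min_drugs) {
    inform(sprintf(
      "category '%s' spans only %d ground-set drug(s) (< %d); discarded",
      category, n_drugs, min_drugs
    ))
    return(NULL)
  }
  structure(
    list(
      pairs = pairs, category = category,
      drugs = sort(unique(pairs$drug_id)),
      genes = sort(unique(pairs$gene_id))
    ),
    class = "pgx_assoc_matrix"
  )
}

#' ROC validation against an external association matrix
#'
#' Computes the AUC of prediction probabilities against the binary truth
#' over the matrix's full drug x gene space; pairs without a prediction
#' receive probability 0 (absence of evidence is the model's genuine
#' output).
#'
#' @param preds prediction tibble `drug_id`, `gene_id`, `probability`.
#' @param truth a [build_external_matrix()] result.
#' @return AUC in \[0, 1\].
#' @export
roc_against_matrix <- function(preds, truth) {
  stopifnot(inherits(truth, "pgx_assoc_matrix"))
  grid <- tidyr::expand_grid(drug_id = truth$drugs, gene_id = truth$genes)
  grid <- grid |>
    mutate(label = as.integer(
      pair_key(.data$drug_id, .data$gene_id) %in%
        pair_key(truth$pairs$drug_id, truth$pairs$gene_id)
    )) |>
    left_join(preds, by = c("drug_id", "gene_id")) |>
    mutate(probability = dplyr::coalesce(.data$probability, 0))
  if (all(grid$label == 0) || all(grid$label == 1)) {
    abort("truth matrix is degenerate (all-zero or all-one)")
  }
  auc_score(grid$label, grid$probability)
}

#' Filter drugs by called-prediction volume
#'
#' Drops drugs whose number of called predictions exceeds `max_preds`
#' (e.g. 600 or 150), and restricts the positive set to the surviving
#' drugs — used to check that promiscuously predicted drugs do not drive
#' performance.
#'
#' @param preds called prediction tibble (`drug_id`, one row per call).
#' @param positives tibble of positive pairs.
#' @param max_preds maximal allowed prediction count per drug (`Inf`
#'   disables filtering).
#' @param drugs drug universe (default: drugs seen in `preds` or
#'   `positives`).
#' @return List with `drugs` (surviving ids), `positives` (restricted),
#'   and the per-drug `counts`.
#' @export
filter_drugs_by_prediction_count <- function(preds, positives, max_preds,
                                             drugs = NULL) {
  drugs <- drugs %||% sort(unique(c(preds$drug_id, positives$drug_id)))
  counts <- tibble(drug_id = drugs) |>
    left_join(count(preds, .data$drug_id, name = "n_predictions"), by = "drug_id") |>
    mutate(n_predictions = dplyr::coalesce(.data$n_predictions, 0L))
  keep <- counts$drug_id[counts$n_predictions <= max_preds]
  list(
    drugs = keep,
    positives = filter(positives, .data$drug_id %in% keep),
    counts = counts
  )
}

#' Upper-tail (accumulative) hypergeometric enrichment test
#'
#' P(X >= k) when drawing `sample_size` items from a universe of
#' `universe_size` items of which `set_size` are marked.
#'
#' @param overlap observed overlap k.
#' @param set_size number of marked items K.
#' @param sample_size number of drawn items n.
#' @param universe_size universe size N.
#' @return Upper-tail p-value (vectorized over its arguments).
#' @export
hypergeometric_enrichment <- function(overlap, set_size, sample_size, universe_size) {
  if (any(overlap > pmin(set_size, sample_size)) ||
      any(set_size > universe_size) || any(sample_size > universe_size) ||
      any(c(overlap, set_size, sample_size, universe_size) < 0)) {
    abort("need overlap <= min(set_size, sample_size) and set/sample <= universe")
  }
  phyper(overlap - 1, set_size, universe_size - set_size, sample_size,
         lower.tail = FALSE)
}

#' Batch enrichment with Benjamini-Hochberg q-values
#'
#' @param batches tibble with columns `overlap`, `set_size`,
#'   `sample_size`, `universe_size` (one row per tested category).
#' @return The input with `p_value` and BH-adjusted `q_value` columns.
#' @export
enrich_test <- function(batches) {
  assert_cols(batches, c("overlap", "set_size", "sample_size", "universe_size"),
              "enrichment batch table")
  batches |>
    mutate(
      p_value = hypergeometric_enrichment(
        .data$overlap, .data$set_size, .data$sample_size, .data$universe_size
      ),
      q_value = p.adjust(.data$p_value, method = "BH")
    )
}
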