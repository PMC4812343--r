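# Negative-pair sampling, Random-Forest training and scoring, and the
# strict-cutoff prediction call.
#
# The classifier is a probability forest: the reported score is the mean
# over trees of the positive-class frequency in the leaf a pair lands in.
# Forest size is pinned at 100 trees and training is seeded and
# single-threaded, so retraining with identical seed, data, and column
# order reproduces identical probabilities.

pair_key <- function(drug_id, gene_id) paste(drug_id, gene_id, sep = "\r")

#' Sample negative candidate pairs
#'
#' Draws `n` drug-gene pairs not present in the positive set, reproducibly
#' under a fixed seed. `"uniform"` samples uniformly over the candidate
#' grid. `"conservation_matched"` controls for yeast-human conservation:
#' gene conservation scores (best-homolog alignment coverage, see
#' [best_homolog_coverage()]) are binned into `n_bins` equal-width bins
#' and negative genes are drawn from each bin proportionally to the bin's
#' representation among the positive genes; drugs are drawn uniformly.
#'
#' @param positives tibble `drug_id`, `gene_id`.
#' @param ground either a `pgx_ground_set`, a list with character vectors
#'   `drugs` and `genes`, or a tibble of candidate pairs.
#' @param n number of negatives to draw.
#' @param mode `"uniform"` or `"conservation_matched"`.
#' @param seed integer seed.
#' @param conservation named numeric vector in \[0, 1\] per gene (required
#'   for matched mode; genes without a significant homolog score 0).
#' @param n_bins number of equal-width conservation bins (default 50).
#' @return Tibble of `n` pairs, disjoint from the positives.
#' @export
sample_negatives <- function(positives, ground, n,
                             mode = c("uniform", "conservation_matched"),
                             seed = 1, conservation = NULL, n_bins = 50) {
  mode <- match.arg(mode)
  if (inherits(ground, "pgx_ground_set")) {
    drugs <- ground$drugs$drug_id
    genes <- ground$human_genes$gene_id
  } else if (is.data.frame(ground)) {
    drugs <- unique(ground$drug_id)
    genes <- unique(ground$gene_id)
  } else {
    drugs <- ground$drugs
    genes <- ground$genes
  }
  pos_keys <- pair_key(positives$drug_id, positives$gene_id)
  n_cand <- length(drugs) * length(genes) - length(unique(pos_keys))
  if (n > n_cand) abort("n exceeds the number of candidate non-positive pairs")

  if (mode == "conservation_matched") {
    if (is.null(conservation)) abort("matched mode needs a conservation score vector")
    cons <- setNames(rep(0, length(genes)), genes)
    known <- intersect(names(conservation), genes)
    cons[known] <- conservation[known]
    breaks <- seq(0, 1, length.out = n_bins + 1)
    bin_of <- function(x) pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
    gene_bins <- bin_of(cons)
    # positives' bins come from the full conservation vector (genes with no
    # score sit in the first bin, like unmatched genes)
    cons_pos <- ifelse(is.na(conservation[positives$gene_id]), 0,
                       conservation[positives$gene_id])
    pos_bins <- bin_of(cons_pos)
    pos_freq <- tabulate(pos_bins, nbins = n_bins)
    pools <- split(genes, gene_bins)
    empty <- setdiff(which(pos_freq > 0), as.integer(names(pools)))
    if (length(empty)) {
      abort(sprintf(
        "positive-occupied conservation bin(s) with no candidate genes: %s",
        paste(empty, collapse = ", ")
      ))
    }
  }

  withr::with_seed(seed, {
    taken <- character(0)
    out_d <- character(0)
    out_g <- character(0)
    guard <- 0L
    while (length(out_d) < n) {
      guard <- guard + 1L
      if (guard > 1000L) abort("negative sampling failed to converge")
      need <- n - length(out_d)
      m <- ceiling(need * 1.3) + 10L
      if (mode == "uniform") {
        d <- drugs[sample.int(length(drugs), m, replace = TRUE)]
        g <- genes[sample.int(length(genes), m, replace = TRUE)]
      } else {
        b <- sample.int(n_bins, m, replace = TRUE, prob = pos_freq)
        g <- map_chr(b, function(bb) {
          pool <- pools[[as.character(bb)]]
          pool[sample.int(length(pool), 1)]
        })
        d <- drugs[sample.int(length(drugs), m, replace = TRUE)]
      }
      keys <- pair_key(d, g)
      ok <- !(keys %in% pos_keys) & !(keys %in% taken) & !duplicated(keys)
      ok_idx <- head(which(ok), need)
      out_d <- c(out_d, d[ok_idx])
      out_g <- c(out_g, g[ok_idx])
      taken <- c(taken, keys[ok_idx])
    }
    tibble(drug_id = out_d, gene_id = out_g)
  })
}

#' Best-homolog conservation score per human gene
#'
#' The maximal alignment coverage over all significant yeast homologs,
#' taken from a sequence similarity matrix; genes with no significant
#' match score 0.
#'
#' @param gene_sim_sequence human x yeast sequence [new_pgx_sim()] matrix.
#' @return Named numeric vector over the matrix's human genes.
#' @export
best_homolog_coverage <- function(gene_sim_sequence) {
  m <- gene_sim_sequence$mat
  setNames(apply(m, 1, max), rownames(m))
}

#' Fit the association probability forest
#'
#' @param features tibble `drug_id`, `gene_id`, plus numeric feature
#'   columns.
#' @param labels logical or 0/1 vector aligned to `features` rows.
#' @param seed integer seed (stored with the model).
#' @param num_trees forest size (default 100).
#' @return A `pgx_rf` model object holding the forest, the feature column
#'   order, and the seed.
#' @export
fit_pgx_forest <- function(features, labels, seed = 1, num_trees = 100) {
  cols <- setdiff(names(features), c("drug_id", "gene_id"))
  if (!length(cols)) abort("no feature columns")
  y <- factor(as.integer(labels), levels = c(0L, 1L))
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("training labels contain a single class")
  }
  x <- as.matrix(features[, cols, drop = FALSE])
  forest <- ranger::ranger(
    x = x, y = y,
    num.trees = num_trees, probability = TRUE, min.node.size = 1,
    importance = "impurity", seed = seed, num.threads = 1
  )
  structure(
    list(forest = forest, feature_cols = cols, seed = seed, num_trees = num_trees,
         n_train = nrow(x)),
    class = "pgx_rf"
  )
}

#' @export
print.pgx_rf <- function(x, ...) {
  cat(sprintf(
    "<pgx_rf> %d trees on %d pairs x %d features (seed %d)\n",
    x$num_trees, x$n_train, length(x$feature_cols), x$seed
  ))
  invisible(x)
}

#' Predict association probabilities
#'
#' @param object a [fit_pgx_forest()] model.
#' @param new_features tibble with the model's feature columns (extra
#'   columns ignored).
#' @param ... unused.
#' @return Numeric vector of positive-class probabilities in \[0, 1\].
#' @export
predict.pgx_rf <- function(object, new_features, ...) {
  x <- as.matrix(new_features[, object$feature_cols, drop = FALSE])
  predict(object$forest, x, num.threads = 1)$predictions[, "1"]
}

#' Broom-style tidier: per-feature importance
#'
#' @param x a `pgx_rf` model.
#' @param ... unused.
#' @return Tibble `term`, `importance` (Gini impurity decrease), sorted.
#' @export
tidy.pgx_rf <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble(term = names(imp), importance = unname(imp)) |>
    arrange(desc(.data$importance))
}

#' Broom-style one-row model summary
#'
#' @param x a `pgx_rf` model.
#' @param ... unused.
#' @return Tibble with forest size, mtry, training size, OOB Brier score.
#' @export
glance.pgx_rf <- function(x, ...) {
  tibble(
    num_trees = x$num_trees,
    mtry = x$forest$mtry,
    n_features = length(x$feature_cols),
    n_train = x$n_train,
    oob_brier = x$forest$prediction.error,
    seed = x$seed
  )
}

#' Train a forest and score query pairs
#'
#' @param features training feature tibble (`drug_id`, `gene_id`, feature
#'   columns).
#' @param labels label vector aligned to the training rows.
#' @param query_features feature tibble of pairs to score; when scoring
#'   novel pairs none of them should appear in the training set.
#' @param seed integer seed.
#' @param num_trees forest size (default 100).
#' @return A `pgx_predictions` tibble: `drug_id`, `gene_id`, `probability`,
#'   with the fitted model in attribute `model`.
#' @export
train_and_score <- function(features, labels, query_features, seed = 1, num_trees = 100) {
  model <- fit_pgx_forest(features, labels, seed = seed, num_trees = num_trees)
  out <- query_features |>
    select("drug_id", "gene_id") |>
    mutate(probability = predict(model, query_features))
  attr(out, "model") <- model
  class(out) <- c("pgx_predictions", class(out))
  out
}

#' Call high-confidence predictions at a strict cutoff
#'
#' Retains pairs with probability at or above the cutoff. A cutoff of 1 is
#' interpreted as tree unanimity, absorbed for floating point as
#' `1 - 1/(2 * num_trees)`. Pairs in the gold standard are flagged
#' `is_known` and excluded from the novel count.
#'
#' @param preds a prediction tibble with `probability`.
#' @param cutoff classification-score cutoff in \[0, 1\] (default 1).
#' @param known gold standard: a `pgx_gold` object or a tibble of pairs.
#' @param num_trees forest size used to absorb unanimity (default 100).
#' @return The retained predictions with an `is_known` flag; the novel
#'   count in attribute `n_novel`.
#' @export
call_top_predictions <- function(preds, cutoff = 1, known = NULL, num_trees = 100) {
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    abort("cutoff must lie in [0, 1]")
  }
  eff <- if (cutoff == 1) 1 - 1 / (2 * num_trees) else cutoff
  known_pairs <- if (inherits(known, "pgx_gold")) known$pairs else known
  known_keys <- if (is.null(known_pairs)) character(0) else {
    pair_key(known_pairs$drug_id, known_pairs$gene_id)
  }
  out <- preds |>
    filter(.data$probability >= eff) |>
    mutate(is_known = pair_key(.data$drug_id, .data$gene_id) %in% known_keys)
  attr(out, "n_novel") <- sum(!out$is_known)
  class(out) <- unique(c("pgx_predictions", class(out)))
  out
}
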