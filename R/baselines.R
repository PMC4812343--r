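# Comparison predictors: the PPI-neighbour (guilt-by-association) method
# and the human-only known-association similarity method, plus the
# valid-set head-to-head protocol that evaluates two methods on the
# intersection of their valid gold-standard pairs.

ppi_adjacency <- function(ppi_edges) {
  assert_cols(ppi_edges, c("gene_a", "gene_b"), "PPI edge list")
  edges <- ppi_edges |>
    filter(.data$gene_a != .data$gene_b) |>
    distinct(.data$gene_a, .data$gene_b)
  both <- bind_rows(
    edges,
    tibble(gene_a = edges$gene_b, gene_b = edges$gene_a)
  ) |> distinct()
  split(both$gene_b, both$gene_a)
}

#' PPI-neighbour baseline features
#'
#' For each query pair (D, G), four features: the maximal (chemical or
#' ATC) similarity between D and any drug associated — by known PGx or by
#' drug-target links — with any immediate PPI neighbour of G. Rests on the
#' assumption that interacting proteins associate with similar drugs.
#' Features are 0 when no neighbour-associated drug exists; a gene absent
#' from the network is invalid (error) and must be excluded from the valid
#' set rather than scored.
#'
#' @param pairs tibble `drug_id`, `gene_id`.
#' @param ppi_edges undirected edge list `gene_a`, `gene_b` (no
#'   self-loops).
#' @param pgx_assoc tibble of known PGx pairs `drug_id`, `gene_id`.
#' @param target_assoc tibble of drug-target pairs `drug_id`, `gene_id`.
#' @param drug_sims named list `chemical`, `atc` of drug similarity
#'   matrices.
#' @return Tibble: `drug_id`, `gene_id`, then `ppi_{chemical,atc}_{pgx,target}`.
#' @export
hansen_features <- function(pairs, ppi_edges, pgx_assoc, target_assoc, drug_sims) {
  assert_cols(pairs, c("drug_id", "gene_id"), "pair table")
  adj <- ppi_adjacency(ppi_edges)
  absent <- setdiff(unique(pairs$gene_id), names(adj))
  if (length(absent)) {
    abort(sprintf(
      "gene(s) absent from the PPI network (invalid for this method): %s",
      paste(head(absent, 5), collapse = ", ")
    ))
  }
  assoc_drugs <- function(assoc, genes) {
    if (is.null(assoc) || nrow(assoc) == 0) return(character(0))
    unique(assoc$drug_id[assoc$gene_id %in% genes])
  }
  ug <- unique(pairs$gene_id)
  nb_drugs <- map(setNames(ug, ug), function(g) {
    nb <- adj[[g]]
    list(pgx = assoc_drugs(pgx_assoc, nb), target = assoc_drugs(target_assoc, nb))
  })
  out <- pairs |> select("drug_id", "gene_id")
  for (dm in c("chemical", "atc")) {
    mat <- drug_sims[[dm]]$mat
    for (at in c("pgx", "target")) {
      out[[paste("ppi", dm, at, sep = "_")]] <- map_dbl(seq_len(nrow(pairs)), function(i) {
        ds <- intersect(nb_drugs[[pairs$gene_id[i]]][[at]], colnames(mat))
        if (!length(ds) || !pairs$drug_id[i] %in% rownames(mat)) return(0)
        max(mat[pairs$drug_id[i], ds])
      })
    }
  }
  out
}

#' Declare a prediction method for head-to-head comparison
#'
#' A method bundles the gene space over which its features are computable
#' (its validity condition) with a feature-building function.
#'
#' @param name method label.
#' @param feature_fun function(pairs) returning a feature tibble
#'   (`drug_id`, `gene_id`, feature columns).
#' @param gene_space character vector of genes the method can score.
#' @param drug_space character vector of drugs the method can score.
#' @return A `pgx_method` object.
#' @export
new_pgx_method <- function(name, feature_fun, gene_space, drug_space) {
  structure(
    list(name = name, features = feature_fun,
         gene_space = gene_space, drug_space = drug_space),
    class = "pgx_method"
  )
}

#' @export
print.pgx_method <- function(x, ...) {
  cat(sprintf("<pgx_method> %s (%d drugs x %d genes scoreable)\n",
              x$name, length(x$drug_space), length(x$gene_space)))
  invisible(x)
}

method_valid <- function(method, pairs) {
  pairs$drug_id %in% method$drug_space & pairs$gene_id %in% method$gene_space
}

#' The yeast-projection method, packaged for comparison
#'
#' Valid pairs are those whose gene has sequence or domain similarity to
#' at least one yeast gene (and whose drug carries both annotations, which
#' holds for every ground-set drug).
#'
#' @param drug_sims,gene_sims,cgi as in [build_feature_matrix()].
#' @return A [new_pgx_method()].
#' @export
pgx_method_yeast <- function(drug_sims, gene_sims, cgi) {
  similar_genes <- sort(unique(unlist(lapply(gene_sims, function(s) {
    rownames(s$mat)[Matrix::rowSums(s$mat) > 0]
  }))))
  drugs <- sort(unique(unlist(lapply(drug_sims, function(s) rownames(s$mat)))))
  new_pgx_method(
    "yeast",
    function(pairs) suppressMessages(
      build_feature_matrix(pairs, drug_sims, gene_sims, cgi)
    ),
    gene_space = similar_genes, drug_space = drugs
  )
}

#' The human-only known-association baseline, packaged for comparison
#'
#' Feature calculation is feasible — the pair is *valid* — only when the
#' query drug has positive similarity to at least one revealed known drug
#' and the query gene to at least one revealed known gene; otherwise every
#' baseline feature is structurally zero. The method's scoreable spaces
#' are derived accordingly from `known_pgx` and the similarity matrices.
#'
#' @param drug_sims named list `chemical`, `atc`.
#' @param human_gene_sims named list `sequence`, `domain` (human x human).
#' @param known_pgx the known associations revealed to the baseline.
#' @return A [new_pgx_method()].
#' @export
pgx_method_human_only <- function(drug_sims, human_gene_sims, known_pgx) {
  reachable <- function(sims, ids) {
    sort(unique(unlist(lapply(sims, function(s) {
      cols <- intersect(ids, colnames(s$mat))
      if (!length(cols)) return(character(0))
      rownames(s$mat)[Matrix::rowSums(s$mat[, cols, drop = FALSE]) > 0]
    }))))
  }
  genes <- reachable(human_gene_sims, unique(known_pgx$gene_id))
  drugs <- reachable(drug_sims, unique(known_pgx$drug_id))
  new_pgx_method(
    "human_only",
    function(pairs) build_baseline_features(pairs, known_pgx, drug_sims, human_gene_sims),
    gene_space = genes, drug_space = drugs
  )
}

#' The PPI-neighbour baseline, packaged for comparison
#'
#' Valid pairs require the gene to have at least one reported interaction.
#'
#' @param ppi_edges undirected edge list `gene_a`, `gene_b`.
#' @param pgx_assoc,target_assoc known association tables.
#' @param drug_sims named list `chemical`, `atc`.
#' @return A [new_pgx_method()].
#' @export
pgx_method_ppi <- function(ppi_edges, pgx_assoc, target_assoc, drug_sims) {
  genes <- sort(names(ppi_adjacency(ppi_edges)))
  drugs <- sort(unique(unlist(lapply(drug_sims, function(s) rownames(s$mat)))))
  new_pgx_method(
    "ppi",
    function(pairs) hansen_features(pairs, ppi_edges, pgx_assoc, target_assoc, drug_sims),
    gene_space = genes, drug_space = drugs
  )
}

#' Valid-set head-to-head comparison of two methods
#'
#' Computes each method's valid gold-standard set, takes the intersection
#' as the common test positives, trains each method's forest on its own
#' valid set minus the intersection plus an equally sized random negative
#' set, and scores both on the intersection plus an equally sized shared
#' negative test set. Train and test sets are disjoint; test negatives are
#' drawn from the gene space both methods can score.
#'
#' @param method_a,method_b [new_pgx_method()] objects.
#' @param gold a `pgx_gold` object or tibble of positive pairs.
#' @param ground a `pgx_ground_set` or list with `drugs`/`genes` vectors.
#' @param seed integer seed.
#' @param num_trees forest size (default 100).
#' @return Tibble with one row per method: `method`, `n_valid`, `n_train`,
#'   `auc`; test-set size in attribute `n_test`.
#' @export
head_to_head <- function(method_a, method_b, gold, ground, seed = 1, num_trees = 100) {
  positives <- if (inherits(gold, "pgx_gold")) gold$pairs else gold
  va <- method_valid(method_a, positives)
  vb <- method_valid(method_b, positives)
  inter <- va & vb
  if (!any(inter)) abort("empty intersection of valid sets")
  train_a <- positives[va & !inter, ]
  train_b <- positives[vb & !inter, ]
  if (nrow(train_a) == 0 || nrow(train_b) == 0) {
    abort("a method has no valid pairs outside the intersection to train on")
  }
  test_pos <- positives[inter, ]

  if (inherits(ground, "pgx_ground_set")) {
    drugs <- ground$drugs$drug_id
    genes <- ground$human_genes$gene_id
  } else {
    drugs <- ground$drugs
    genes <- ground$genes
  }
  shared_genes <- intersect(intersect(genes, method_a$gene_space), method_b$gene_space)
  shared_drugs <- intersect(intersect(drugs, method_a$drug_space), method_b$drug_space)
  n_test <- nrow(test_pos)
  test_neg <- sample_negatives(
    positives, list(drugs = shared_drugs, genes = shared_genes),
    n_test, seed = child_seed(seed, 1L)
  )

  score_method <- function(method, train_pos, n_valid, offset) {
    train_neg <- sample_negatives(
      bind_rows(positives, test_neg),
      list(
        drugs = intersect(drugs, method$drug_space),
        genes = intersect(genes, method$gene_space)
      ),
      nrow(train_pos), seed = child_seed(seed, offset)
    )
    train_pairs <- bind_rows(train_pos, train_neg)
    labels <- rep(c(1L, 0L), c(nrow(train_pos), nrow(train_neg)))
    test_pairs <- bind_rows(test_pos, test_neg)
    test_labels <- rep(c(1L, 0L), c(nrow(test_pos), nrow(test_neg)))
    preds <- train_and_score(
      method$features(train_pairs), labels, method$features(test_pairs),
      seed = seed, num_trees = num_trees
    )
    tibble(
      method = method$name,
      n_valid = n_valid,
      n_train = nrow(train_pos),
      auc = auc_score(test_labels, preds$probability)
    )
  }

  out <- bind_rows(
    score_method(method_a, train_a, sum(va), 2L),
    score_method(method_b, train_b, sum(vb), 3L)
  )
  attr(out, "n_test") <- n_test
  out
}
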