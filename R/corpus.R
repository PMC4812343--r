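# Ground-set assembly and the gold-standard positive set.
#
# The ground set is the universe over which predictions are defined: drugs
# carrying both a SMILES structure and at least one ATC code (so both drug
# similarity measures are computable) and human genes reachable by at least
# one gene-similarity source. All identifiers are case-sensitive opaque
# strings; no identifier mapping is attempted.

#' Assemble the prediction ground set
#'
#' Drugs are retained iff they have a non-empty SMILES string and at least
#' one ATC code. Human genes are retained iff they appear in at least one
#' gene-similarity source: a significant alignment record or a non-empty
#' domain annotation.
#'
#' @param drug_records tibble with `drug_id`, `smiles`, and either an `atc`
#'   list-column or a semicolon-separated `atc_codes` column. Optional
#'   list-column `fp` (fingerprint bit sets) is carried through.
#' @param human_gene_records tibble with `gene_id` and a `domains`
#'   list-column (or semicolon-separated `domain_ids`).
#' @param yeast_gene_records tibble with `gene_id`, `protein_length`, and
#'   `domains`/`domain_ids`.
#' @param alignments optional alignment tibble (`human_gene_id`, `e_value`);
#'   used as the sequence-similarity evidence source for gene retention.
#' @param e_cutoff E-value threshold for counting an alignment as evidence.
#' @return A `pgx_ground_set`: list of tibbles `drugs`, `human_genes`,
#'   `yeast_genes`, plus retention `counts`.
#' @export
build_ground_set <- function(drug_records, human_gene_records, yeast_gene_records,
                             alignments = NULL, e_cutoff = 0.01) {
  assert_cols(drug_records, c("drug_id", "smiles"), "drug table")
  assert_cols(human_gene_records, "gene_id", "human gene table")
  assert_cols(yeast_gene_records, c("gene_id", "protein_length"), "yeast gene table")

  drugs <- as_tibble(drug_records)
  if (!"atc" %in% names(drugs)) {
    assert_cols(drugs, "atc_codes", "drug table")
    drugs$atc <- split_semi(drugs$atc_codes)
    drugs$atc_codes <- NULL
  }
  dup <- drugs |>
    distinct(.data$drug_id, .data$smiles) |>
    count(.data$drug_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicate drug_id with conflicting SMILES: %s",
      paste(dup$drug_id, collapse = ", ")
    ))
  }
  drugs <- distinct(drugs, .data$drug_id, .keep_all = TRUE)
  n_drugs_in <- nrow(drugs)
  drugs <- filter(
    drugs,
    !is.na(.data$smiles), nzchar(.data$smiles), lengths(.data$atc) > 0
  )

  fix_domains <- function(genes) {
    if (!"domains" %in% names(genes)) {
      assert_cols(genes, "domain_ids", "gene table")
      genes$domains <- split_semi(genes$domain_ids)
      genes$domain_ids <- NULL
    }
    genes
  }
  human <- fix_domains(as_tibble(human_gene_records))
  yeast <- fix_domains(as_tibble(yeast_gene_records))
  if (any(yeast$protein_length <= 0)) abort("yeast protein_length must be positive")

  aligned_ids <- character(0)
  if (!is.null(alignments) && nrow(alignments) > 0) {
    aligned_ids <- unique(alignments$human_gene_id[alignments$e_value < e_cutoff])
  }
  n_human_in <- nrow(human)
  human <- filter(human, lengths(.data$domains) > 0 | .data$gene_id %in% aligned_ids)

  counts <- c(
    drugs_in = n_drugs_in, drugs_kept = nrow(drugs),
    human_genes_in = n_human_in, human_genes_kept = nrow(human),
    yeast_genes = nrow(yeast)
  )
  inform(sprintf(
    "ground set: %d/%d drugs with SMILES+ATC, %d/%d human genes with similarity evidence",
    counts[["drugs_kept"]], counts[["drugs_in"]],
    counts[["human_genes_kept"]], counts[["human_genes_in"]]
  ))
  structure(
    list(drugs = drugs, human_genes = human, yeast_genes = yeast, counts = counts),
    class = "pgx_ground_set"
  )
}

#' @export
print.pgx_ground_set <- function(x, ...) {
  cat(sprintf(
    "<pgx_ground_set> %d drugs, %d human genes, %d yeast genes\n",
    nrow(x$drugs), nrow(x$human_genes), nrow(x$yeast_genes)
  ))
  invisible(x)
}

#' Load the gold-standard positive associations
#'
#' Combines direct drug-gene associations with associations extrapolated
#' from drug-class records (every member drug of an associated class
#' inherits the gene association), deduplicates, and restricts everything
#' to the ground set.
#'
#' @param direct_table tibble `drug_id`, `gene_id`.
#' @param class_table tibble `class_id`, `gene_id`.
#' @param class_membership tibble `class_id`, `drug_id`.
#' @param ground_set a [build_ground_set()] result.
#' @return A `pgx_gold` object: list with `pairs` (extrapolated, deduped,
#'   ground-restricted), `direct` (the direct-only subset), `class_records`,
#'   and `class_members`.
#' @export
load_gold_standard <- function(direct_table, class_table, class_membership, ground_set) {
  assert_cols(direct_table, c("drug_id", "gene_id"), "direct gold table")
  assert_cols(class_table, c("class_id", "gene_id"), "class gold table")
  assert_cols(class_membership, c("class_id", "drug_id"), "class membership table")

  orphan <- setdiff(class_table$class_id, class_membership$class_id)
  if (length(orphan)) {
    warn(sprintf(
      "skipping %d class record(s) with no membership entry: %s",
      length(orphan), paste(orphan, collapse = ", ")
    ))
    class_table <- filter(class_table, !.data$class_id %in% orphan)
  }

  extrapolated <- class_table |>
    inner_join(class_membership, by = "class_id",
               relationship = "many-to-many") |>
    select("drug_id", "gene_id")

  restrict <- function(pairs) {
    pairs |>
      filter(
        .data$drug_id %in% ground_set$drugs$drug_id,
        .data$gene_id %in% ground_set$human_genes$gene_id
      ) |>
      distinct(.data$drug_id, .data$gene_id)
  }
  direct <- restrict(select(direct_table, "drug_id", "gene_id"))
  pairs <- restrict(bind_rows(select(direct_table, "drug_id", "gene_id"), extrapolated))

  structure(
    list(
      pairs = pairs, direct = direct,
      class_records = as_tibble(class_table),
      class_members = as_tibble(class_membership)
    ),
    class = "pgx_gold"
  )
}

#' @export
print.pgx_gold <- function(x, ...) {
  cat(sprintf(
    "<pgx_gold> %d positive pairs (%d direct, %d class-extrapolated)\n",
    nrow(x$pairs), nrow(x$direct), nrow(x$pairs) - nrow(x$direct)
  ))
  invisible(x)
}

#' Candidate-pair bookkeeping over the ground set
#'
#' Number of drug x gene candidate pairs and of negative candidates
#' (candidates not in the positive set).
#'
#' @param n_drugs,n_human_genes ground-set sizes.
#' @param n_positives size of the gold-standard positive set.
#' @return Tibble with `candidate_pairs` and `negative_candidates`.
#' @export
count_candidate_pairs <- function(n_drugs, n_human_genes, n_positives = 0) {
  stopifnot(n_positives <= n_drugs * n_human_genes)
  tibble(
    candidate_pairs = as.numeric(n_drugs) * n_human_genes,
    negative_candidates = as.numeric(n_drugs) * n_human_genes - n_positives
  )
}
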