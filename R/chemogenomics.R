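# Preparation of HIP/HOP chemogenomic screens: condition-to-drug mapping,
# highest-concentration selection, [0,1] normalization, and the 5%-load
# robustness filter.
#
# HIP (haploinsufficiency) profiles measure fitness of heterozygous
# deletion strains under drug and cover essential genes; HOP (homozygote)
# profiles cover non-essential genes. Raw per-source scores (log2 ratios,
# MADL, FD-scores) are treated as opaque reals.

#' Construct a chemogenomic dataset
#'
#' @param source_name screen source label (e.g. one of three screens).
#' @param assay `"HIP"` or `"HOP"`.
#' @param scores tibble `yeast_gene_id`, `drug_id`, `raw_score` and, once
#'   normalized, `score` in \[0, 1\].
#' @param normalized logical; whether `score` holds normalized values.
#' @return A `pgx_cgi` object.
#' @export
new_pgx_cgi <- function(source_name, assay, scores, normalized = FALSE) {
  if (!assay %in% c("HIP", "HOP")) abort("assay must be exactly one of HIP/HOP")
  assert_cols(scores, c("yeast_gene_id", "drug_id", "raw_score"), "cgi scores")
  structure(
    list(source = source_name, assay = assay,
         scores = as_tibble(scores), normalized = normalized),
    class = "pgx_cgi"
  )
}

#' @export
print.pgx_cgi <- function(x, ...) {
  cat(sprintf(
    "<pgx_cgi> %s %s: %d genes x %d drugs (%s)\n",
    x$source, x$assay,
    dplyr::n_distinct(x$scores$yeast_gene_id),
    dplyr::n_distinct(x$scores$drug_id),
    if (x$normalized) "normalized" else "raw"
  ))
  invisible(x)
}

#' Select the highest-concentration condition per drug
#'
#' When a drug was screened under several conditions, the experiment with
#' the highest concentration represents the drug effect. Ties are broken by
#' the lexicographically smallest condition id; drugs whose concentrations
#' are all unparsable keep their first condition by id, with a warning.
#'
#' @param conditions tibble `condition_id`, `drug_id`, `concentration`,
#'   `assay`, and optionally `source`.
#' @return Tibble with exactly one condition per (source, assay, drug).
#' @export
select_highest_concentration <- function(conditions) {
  assert_cols(conditions, c("condition_id", "drug_id", "concentration", "assay"),
              "condition table")
  if (any(is.na(conditions$drug_id) | !nzchar(conditions$drug_id))) {
    abort("every condition must be mapped to a drug")
  }
  if (!"source" %in% names(conditions)) conditions$source <- "default"
  grouped <- conditions |>
    group_by(.data$source, .data$assay, .data$drug_id)
  bad <- grouped |>
    summarise(all_na = all(is.na(.data$concentration)), .groups = "drop") |>
    filter(.data$all_na)
  if (nrow(bad)) {
    warn(sprintf(
      "%d drug(s) with no parsable concentration; keeping first condition by id",
      nrow(bad)
    ))
  }
  grouped |>
    arrange(desc(dplyr::coalesce(.data$concentration, -Inf)), .data$condition_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Normalize a chemogenomic dataset to \[0, 1\]
#'
#' Divides the absolute value of every score by the maximal absolute score
#' in the whole dataset (per source and assay, not per drug). The operation
#' is idempotent and scale-invariant; an all-zero dataset stays all-zero.
#' Direction of the effect (sensitivity vs resistance) is not retained.
#'
#' @param ds a [new_pgx_cgi()] object with raw scores.
#' @return The dataset with a normalized `score` column.
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "pgx_cgi"))
  raw <- ds$scores$raw_score
  bad <- which(!is.finite(raw))
  if (length(bad)) {
    cell <- ds$scores[bad[1], ]
    abort(sprintf(
      "non-finite raw score at (%s, %s) in %s %s",
      cell$yeast_gene_id, cell$drug_id, ds$source, ds$assay
    ))
  }
  m <- if (nrow(ds$scores)) max(abs(raw)) else 0
  ds$scores$score <- if (m > 0) abs(raw) / m else abs(raw)
  ds$normalized <- TRUE
  ds
}

#' Drop the highest-load drugs from a dataset
#'
#' Per-drug load is the sum of normalized scores over yeast genes; the
#' `ceiling(fraction * n_drugs)` drugs with the highest load are removed
#' (ties broken by load, then drug id). Used to verify robustness of the
#' downstream classifier to screen-wide strong responders.
#'
#' @param ds a normalized [new_pgx_cgi()] dataset.
#' @param fraction fraction of drugs to remove, in (0, 1); default 0.05.
#' @return The dataset without the removed drugs; removed ids in attribute
#'   `removed_drugs`.
#' @export
drop_high_load_drugs <- function(ds, fraction = 0.05) {
  stopifnot(inherits(ds, "pgx_cgi"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("fraction must lie in (0, 1)")
  }
  if (!ds$normalized) abort("dataset must be normalized before load filtering")
  loads <- ds$scores |>
    group_by(.data$drug_id) |>
    summarise(load = sum(.data$score), .groups = "drop") |>
    arrange(desc(.data$load), .data$drug_id)
  n_remove <- ceiling(fraction * nrow(loads))
  removed <- head(loads$drug_id, n_remove)
  ds$scores <- filter(ds$scores, !.data$drug_id %in% removed)
  attr(ds, "removed_drugs") <- removed
  ds
}

#' Prepare chemogenomic datasets from condition-level score tables
#'
#' Joins per-condition scores to condition metadata, drops conditions not
#' mapped to a ground-set drug, keeps the highest-concentration condition
#' per (source, assay, drug), splits by source and assay, and normalizes
#' each resulting dataset.
#'
#' @param scores tibble `yeast_gene_id`, `condition_id`, `raw_score`.
#' @param conditions tibble `condition_id`, `drug_id`, `concentration`,
#'   `assay`, `source`.
#' @param drug_ids optional character vector restricting to ground-set
#'   drugs (conditions for other drugs are dropped with a message).
#' @return Named list of normalized `pgx_cgi` datasets
#'   (`"<source>_<assay>"`).
#' @export
prepare_cgi <- function(scores, conditions, drug_ids = NULL) {
  assert_cols(scores, c("yeast_gene_id", "condition_id", "raw_score"), "cgi scores")
  assert_cols(conditions, c("condition_id", "drug_id", "concentration", "assay", "source"),
              "condition table")
  mapped <- filter(conditions, !is.na(.data$drug_id), nzchar(.data$drug_id))
  if (!is.null(drug_ids)) mapped <- filter(mapped, .data$drug_id %in% drug_ids)
  if (nrow(mapped) < nrow(conditions)) {
    inform(sprintf(
      "dropping %d condition(s) not mapped to a ground-set drug",
      nrow(conditions) - nrow(mapped)
    ))
  }
  chosen <- select_highest_concentration(mapped)
  long <- scores |>
    inner_join(select(chosen, "condition_id", "drug_id", "assay", "source"),
               by = "condition_id")
  split_keys <- long |> distinct(.data$source, .data$assay) |> arrange(.data$source, .data$assay)
  out <- pmap(split_keys, function(source, assay) {
    sub <- filter(long, .data$source == !!source, .data$assay == !!assay)
    normalize_dataset(new_pgx_cgi(
      source, assay,
      select(sub, "yeast_gene_id", "drug_id", "raw_score")
    ))
  })
  names(out) <- paste(split_keys$source, split_keys$assay, sep = "_")
  out
}
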