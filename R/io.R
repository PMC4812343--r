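# Flat-file serialization of a corpus bundle. All files are plain TSV;
# set-valued fields (ATC codes, domains, fingerprint bits) are
# semicolon-separated. read_corpus() re-runs the ground-set, gold-standard
# and chemogenomic preparation steps of the package on the parsed tables,
# so a written corpus round-trips through the same readers real data
# would use.

#' Write a corpus bundle to flat files
#'
#' @param corpus a `pgx_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) readr::write_tsv(df, file.path(dir, name))
  w(corpus$drugs |>
      mutate(atc_codes = join_semi(.data$atc)) |>
      select("drug_id", "smiles", "atc_codes"), "drugs.tsv")
  w(corpus$drugs |>
      mutate(bits = join_semi(map(.data$fp, as.character))) |>
      select("drug_id", "bits", "nbits"), "fingerprints.tsv")
  w(corpus$human_genes |>
      mutate(domain_ids = join_semi(.data$domains)) |>
      select("gene_id", "protein_length", "domain_ids"), "genes_human.tsv")
  w(corpus$yeast_genes |>
      mutate(domain_ids = join_semi(.data$domains)) |>
      select("gene_id", "protein_length", "domain_ids"), "genes_yeast.tsv")
  w(corpus$alignments, "alignments.tsv")
  w(corpus$alignments_human, "alignments_human.tsv")
  w(corpus$gold$direct, "gold_direct.tsv")
  w(corpus$gold$class_records, "gold_class.tsv")
  w(corpus$gold$class_members, "class_members.tsv")
  w(corpus$cgi_scores, "cgi_scores.tsv")
  w(corpus$cgi_conditions, "cgi_conditions.tsv")
  w(corpus$ppi, "ppi_edges.tsv")
  w(corpus$targets, "targets.tsv")
  jsonlite::write_json(unclass(corpus$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a corpus bundle from flat files
#'
#' Parses the tables written by [write_corpus()] and re-runs ground-set
#' assembly, gold-standard extrapolation, and chemogenomic preparation.
#'
#' @param dir directory holding the flat files.
#' @return A `pgx_corpus`.
#' @export
read_corpus <- function(dir) {
  r <- function(name, col_types) {
    readr::read_tsv(file.path(dir, name), col_types = col_types, progress = FALSE)
  }
  drugs <- r("drugs.tsv", readr::cols(
    drug_id = "c", smiles = "c", atc_codes = "c"
  ))
  fps <- r("fingerprints.tsv", readr::cols(drug_id = "c", bits = "c", nbits = "i"))
  drugs <- drugs |>
    left_join(fps, by = "drug_id") |>
    mutate(
      atc = split_semi(.data$atc_codes),
      fp = map(split_semi(.data$bits), as.integer)
    ) |>
    select("drug_id", "smiles", "atc", "fp", "nbits")
  gene_cols <- readr::cols(gene_id = "c", protein_length = "i", domain_ids = "c")
  human <- r("genes_human.tsv", gene_cols) |>
    mutate(domains = split_semi(.data$domain_ids)) |>
    select("gene_id", "protein_length", "domains")
  yeast <- r("genes_yeast.tsv", gene_cols) |>
    mutate(domains = split_semi(.data$domain_ids)) |>
    select("gene_id", "protein_length", "domains")
  alignments <- r("alignments.tsv", readr::cols(
    yeast_gene_id = "c", human_gene_id = "c", aligned_span = "d", e_value = "d"
  ))
  alignments_human <- r("alignments_human.tsv", readr::cols(
    query_id = "c", subject_id = "c", aligned_span = "d", e_value = "d"
  ))
  pair_cols <- readr::cols(drug_id = "c", gene_id = "c")
  ground <- build_ground_set(drugs, human, yeast, alignments)
  gold <- load_gold_standard(
    r("gold_direct.tsv", pair_cols),
    r("gold_class.tsv", readr::cols(class_id = "c", gene_id = "c")),
    r("class_members.tsv", readr::cols(class_id = "c", drug_id = "c")),
    ground
  )
  cgi_scores <- r("cgi_scores.tsv", readr::cols(
    yeast_gene_id = "c", condition_id = "c", raw_score = "d"
  ))
  cgi_conditions <- r("cgi_conditions.tsv", readr::cols(
    condition_id = "c", drug_id = "c", concentration = "d",
    assay = "c", source = "c"
  ))
  cgi <- prepare_cgi(cgi_scores, cgi_conditions, drug_ids = ground$drugs$drug_id)
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- do.call(simulation_config, cfg_raw)
  structure(
    list(
      drugs = ground$drugs, human_genes = ground$human_genes,
      yeast_genes = ground$yeast_genes,
      alignments = alignments, alignments_human = alignments_human,
      gold = gold, cgi = cgi,
      cgi_scores = cgi_scores, cgi_conditions = cgi_conditions,
      ppi = r("ppi_edges.tsv", readr::cols(gene_a = "c", gene_b = "c")),
      targets = r("targets.tsv", pair_cols),
      config = cfg
    ),
    class = "pgx_corpus"
  )
}

#' Write a similarity matrix as a three-column TSV
#'
#' @param sim a [new_pgx_sim()] object.
#' @param path output file (`row_id`, `col_id`, `score`).
#' @return `path`, invisibly.
#' @export
write_sim <- function(sim, path) {
  readr::write_tsv(as_tibble(sim), path)
  invisible(path)
}

#' Read a similarity matrix from a three-column TSV
#'
#' @param path file written by [write_sim()].
#' @param measure measure tag to record.
#' @param row_ids,col_ids optional full id spaces (defaults to the ids
#'   present in the file).
#' @return A [new_pgx_sim()] object.
#' @export
read_sim <- function(path, measure = "unknown", row_ids = NULL, col_ids = NULL) {
  trip <- readr::read_tsv(path, col_types = readr::cols(
    row_id = "c", col_id = "c", score = "d"
  ), progress = FALSE)
  row_ids <- row_ids %||% sort(unique(trip$row_id))
  col_ids <- col_ids %||% sort(unique(trip$col_id))
  mat <- Matrix::sparseMatrix(
    i = match(trip$row_id, row_ids), j = match(trip$col_id, col_ids),
    x = trip$score, dims = c(length(row_ids), length(col_ids)),
    dimnames = list(row_ids, col_ids)
  )
  new_pgx_sim(mat, measure)
}
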