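# The core feature score. A candidate association between drug D and human
# gene G is scored against a chemogenomic screen by
#
#   max over screened (d, g) of ( drugSim(D, d) * geneSim(G, g) * CGI(d, g) )^(1/3)
#
# i.e. the maximal geometric mean of drug similarity, cross-species gene
# similarity, and normalized chemogenomic response. The maximum picks the
# most similar screened drug-gene pair with an observable response,
# suppressing noise from non-responding genes (any zero factor kills the
# product) and from dissimilar drugs or genes. Combining 2 drug measures x
# 2 gene measures x 2 assays gives 8 features per screen source, 24 over
# three sources; the classifier weighs them.

feature_col_name <- function(source, drug_measure, gene_measure, assay) {
  paste(source, drug_measure, gene_measure, tolower(assay), sep = "_")
}

#' Enumerate feature definitions for a set of chemogenomic datasets
#'
#' @param cgi named list of [new_pgx_cgi()] datasets.
#' @return Tibble with one row per feature column, in the deterministic
#'   order used by [build_feature_matrix()]: source (order of first
#'   appearance), then drug measure (chemical, atc), gene measure
#'   (sequence, domain), assay (hip, hop).
#' @export
feature_definitions <- function(cgi) {
  sources <- unique(map_chr(cgi, "source"))
  grid <- tidyr::expand_grid(
    source = sources,
    drug_measure = c("chemical", "atc"),
    gene_measure = c("sequence", "domain"),
    assay = c("HIP", "HOP")
  )
  avail <- tibble(
    source = map_chr(cgi, "source"),
    assay = map_chr(cgi, "assay")
  )
  grid |>
    inner_join(distinct(avail), by = c("source", "assay")) |>
    mutate(column = feature_col_name(.data$source, .data$drug_measure,
                                     .data$gene_measure, .data$assay))
}

# dense yeast-gene x drug score matrix of one chemogenomic dataset
cgi_dense <- function(ds) {
  g <- sort(unique(ds$scores$yeast_gene_id))
  d <- sort(unique(ds$scores$drug_id))
  C <- matrix(0, length(g), length(d), dimnames = list(g, d))
  C[cbind(match(ds$scores$yeast_gene_id, g), match(ds$scores$drug_id, d))] <-
    ds$scores$score
  C
}

#' Score one candidate association against one chemogenomic dataset
#'
#' The maximal geometric mean of drug similarity, gene similarity, and
#' normalized chemogenomic score over all screened (drug, yeast gene)
#' pairs. Returns 0 when no triple has all three factors positive; a query
#' drug or gene outside the similarity row space scores 0 with a warning
#' (the pair has no evidence).
#'
#' @param drug_id,gene_id the query pair.
#' @param drug_sim drug x drug [new_pgx_sim()] matrix.
#' @param gene_sim human x yeast [new_pgx_sim()] matrix.
#' @param cgi a normalized [new_pgx_cgi()] dataset.
#' @return Score in \[0, 1\].
#' @export
feature_score <- function(drug_id, gene_id, drug_sim, gene_sim, cgi) {
  stopifnot(inherits(cgi, "pgx_cgi"))
  if (!cgi$normalized) abort("chemogenomic dataset must be normalized")
  missing <- c(
    if (!drug_id %in% rownames(drug_sim$mat)) drug_id,
    if (!gene_id %in% rownames(gene_sim$mat)) gene_id
  )
  if (length(missing)) {
    warn(sprintf("no similarity evidence for: %s (score 0)",
                 paste(missing, collapse = ", ")))
    return(0)
  }
  s <- cgi$scores
  ds <- sim_row_vec(drug_sim, drug_id)
  gs <- sim_row_vec(gene_sim, gene_id)
  d_ok <- s$drug_id %in% names(ds)
  g_ok <- s$yeast_gene_id %in% names(gs)
  prod <- numeric(nrow(s))
  ok <- d_ok & g_ok
  prod[ok] <- ds[s$drug_id[ok]] * gs[s$yeast_gene_id[ok]] * s$score[ok]
  if (!length(prod) || max(prod) <= 0) return(0)
  max(prod)^(1 / 3)
}

#' Build the candidate-pair feature matrix
#'
#' One row per candidate (drug, gene) pair and one column per feature:
#' 8 features per available chemogenomic dataset source (2 drug measures x
#' 2 gene measures x 2 assays), 24 over three sources. Values in \[0, 1\].
#'
#' @param pairs tibble `drug_id`, `gene_id` (non-empty).
#' @param drug_sims named list: `chemical`, `atc` drug similarity matrices.
#' @param gene_sims named list: `sequence`, `domain` human x yeast
#'   similarity matrices.
#' @param cgi named list of normalized [new_pgx_cgi()] datasets.
#' @return Tibble: `drug_id`, `gene_id`, then feature columns named
#'   `{source}_{drug_measure}_{gene_measure}_{assay}` in deterministic
#'   order.
#' @export
build_feature_matrix <- function(pairs, drug_sims, gene_sims, cgi) {
  assert_cols(pairs, c("drug_id", "gene_id"), "pair table")
  if (nrow(pairs) == 0) abort("empty pair list")
  stopifnot(all(c("chemical", "atc") %in% names(drug_sims)),
            all(c("sequence", "domain") %in% names(gene_sims)),
            length(cgi) > 0)
  if (any(!map_chr(cgi, "assay") %in% c("HIP", "HOP"))) abort("invalid assay tag")
  if (any(!map_lgl(cgi, function(d) d$normalized))) {
    abort("all chemogenomic datasets must be normalized")
  }

  ud <- unique(pairs$drug_id)
  ug <- unique(pairs$gene_id)
  no_drug <- setdiff(ud, Reduce(union, lapply(drug_sims, function(s) rownames(s$mat))))
  no_gene <- setdiff(ug, Reduce(union, lapply(gene_sims, function(s) rownames(s$mat))))
  if (length(no_drug) || length(no_gene)) {
    warn(sprintf(
      "%d drug(s) and %d gene(s) outside the similarity row spaces score 0 everywhere",
      length(no_drug), length(no_gene)
    ))
  }

  defs <- feature_definitions(cgi)
  di <- match(pairs$drug_id, ud)
  gi <- match(pairs$gene_id, ug)
  out <- pairs |> select("drug_id", "gene_id")

  key <- paste(map_chr(cgi, "source"), map_chr(cgi, "assay"), sep = "_")
  for (src in unique(defs$source)) {
    for (assay in c("HIP", "HOP")) {
      idx <- which(key == paste(src, assay, sep = "_"))
      if (!length(idx)) next
      C <- cgi_dense(cgi[[idx[1]]])
      for (gm in c("sequence", "domain")) {
        GS <- sim_rows(gene_sims[[gm]], ug, cols = rownames(C))
        T_ <- max_times(GS, C) # gene x screened-drug partial maxima
        for (dm in c("chemical", "atc")) {
          DS <- sim_rows(drug_sims[[dm]], ud, cols = colnames(C))
          grid <- max_times(DS, t(T_)) # drug x gene full grid
          out[[feature_col_name(src, dm, gm, assay)]] <-
            grid[cbind(di, gi)]^(1 / 3)
        }
      }
    }
  }
  out <- out[, c("drug_id", "gene_id", defs$column)]
  inform(sprintf("feature matrix: %d pairs x %d feature columns",
                 nrow(out), ncol(out) - 2L))
  out
}

#' Human-only baseline similarity score
#'
#' Scores a candidate pair by its similarity to known human PGx
#' associations only, without chemogenomic evidence: the maximal geometric
#' mean (square root of the product) of drug similarity and human-human
#' gene similarity over all known associations. Used to quantify the added
#' value of the yeast screens.
#'
#' @param drug_id,gene_id the query pair.
#' @param known_pgx tibble `drug_id`, `gene_id` of known associations;
#'   must exclude the query pair itself when used in evaluation.
#' @param drug_sim drug x drug similarity matrix.
#' @param human_gene_sim human x human similarity matrix.
#' @return Score in \[0, 1\]; 0 for an empty known set.
#' @export
human_baseline_score <- function(drug_id, gene_id, known_pgx, drug_sim, human_gene_sim) {
  if (is.null(known_pgx) || nrow(known_pgx) == 0) return(0)
  ds <- sim_row_vec(drug_sim, drug_id)
  gs <- sim_row_vec(human_gene_sim, gene_id)
  ok <- known_pgx$drug_id %in% names(ds) & known_pgx$gene_id %in% names(gs)
  if (!any(ok)) return(0)
  prod <- ds[known_pgx$drug_id[ok]] * gs[known_pgx$gene_id[ok]]
  if (max(prod) <= 0) return(0)
  sqrt(max(prod))
}

#' Build the human-only baseline feature matrix
#'
#' Four features per pair (2 drug measures x 2 human gene measures), each
#' the maximal geometric mean of drug and gene similarity to a known PGx
#' association. When a query pair is itself in the known set it is excluded
#' from its own evidence.
#'
#' @param pairs tibble `drug_id`, `gene_id`.
#' @param known_pgx tibble `drug_id`, `gene_id` of known associations.
#' @param drug_sims named list `chemical`, `atc`.
#' @param human_gene_sims named list `sequence`, `domain` (human x human).
#' @param exclude_self drop the query pair from its own evidence set
#'   (default TRUE).
#' @return Tibble: `drug_id`, `gene_id`, then columns
#'   `human_{drug_measure}_{gene_measure}`.
#' @export
build_baseline_features <- function(pairs, known_pgx, drug_sims, human_gene_sims,
                                    exclude_self = TRUE) {
  assert_cols(pairs, c("drug_id", "gene_id"), "pair table")
  if (nrow(pairs) == 0) abort("empty pair list")
  out <- pairs |> select("drug_id", "gene_id")
  cols <- tidyr::expand_grid(dm = c("chemical", "atc"), gm = c("sequence", "domain"))

  empty_known <- is.null(known_pgx) || nrow(known_pgx) == 0
  if (!empty_known) {
    kd <- unique(known_pgx$drug_id)
    kg <- unique(known_pgx$gene_id)
    C <- matrix(0, length(kg), length(kd), dimnames = list(kg, kd))
    C[cbind(match(known_pgx$gene_id, kg), match(known_pgx$drug_id, kd))] <- 1
    ud <- unique(pairs$drug_id)
    ug <- unique(pairs$gene_id)
    di <- match(pairs$drug_id, ud)
    gi <- match(pairs$gene_id, ug)
    self <- which(paste(pairs$drug_id, pairs$gene_id) %in%
                    paste(known_pgx$drug_id, known_pgx$gene_id))
  }

  for (i in seq_len(nrow(cols))) {
    dm <- cols$dm[i]
    gm <- cols$gm[i]
    nm <- paste("human", dm, gm, sep = "_")
    if (empty_known) {
      out[[nm]] <- 0
      next
    }
    GS <- sim_rows(human_gene_sims[[gm]], ug, cols = kg)
    DS <- sim_rows(drug_sims[[dm]], ud, cols = kd)
    grid <- max_times(DS, t(max_times(GS, C)))
    v <- grid[cbind(di, gi)]
    if (exclude_self && length(self)) {
      for (s in self) {
        kk <- known_pgx |>
          filter(!(.data$drug_id == pairs$drug_id[s] & .data$gene_id == pairs$gene_id[s]))
        v[s] <- human_baseline_score(pairs$drug_id[s], pairs$gene_id[s], kk,
                                     drug_sims[[dm]], human_gene_sims[[gm]])^2
      }
    }
    out[[nm]] <- sqrt(pmax(v, 0))
  }
  out
}
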