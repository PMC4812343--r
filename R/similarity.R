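# Similarity measures: chemical Tanimoto, ATC-hierarchy, yeast->human
# alignment coverage, and cross-species domain Jaccard. All measures are
# normalized to [0, 1]. Matrices are stored sparsely (absent entry = 0) and
# are many-to-many: every pair with a positive score is kept, not only
# best hits.

#' Construct a similarity matrix container
#'
#' Thin wrapper around a sparse `Matrix::dgCMatrix` with a recorded measure
#' name. Absent entries mean similarity 0.
#'
#' @param mat matrix or sparse Matrix with dimnames set.
#' @param measure character tag, e.g. `"chemical"`, `"atc"`, `"sequence"`,
#'   `"domain"`.
#' @return A `pgx_sim` object.
#' @export
new_pgx_sim <- function(mat, measure) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  mat <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (length(mat@x) && (min(mat@x) < 0 || max(mat@x) > 1)) {
    abort("similarity scores must lie in [0, 1]")
  }
  structure(list(mat = mat, measure = measure), class = "pgx_sim")
}

#' @export
print.pgx_sim <- function(x, ...) {
  cat(sprintf(
    "<pgx_sim> %s: %d x %d, %d stored entries\n",
    x$measure, nrow(x$mat), ncol(x$mat), length(x$mat@x)
  ))
  invisible(x)
}

#' @export
dim.pgx_sim <- function(x) dim(x$mat)

#' Tidy a similarity matrix into a sparse triplet tibble
#'
#' @param x a `pgx_sim` object.
#' @param ... unused.
#' @return Tibble with columns `row_id`, `col_id`, `score` (stored entries
#'   only; unlisted pairs have score 0).
#' @export
as_tibble.pgx_sim <- function(x, ...) {
  trip <- Matrix::summary(x$mat)
  tibble(
    row_id = rownames(x$mat)[trip$i],
    col_id = colnames(x$mat)[trip$j],
    score = trip$x
  )
}

# dense rows of a similarity matrix for a set of (possibly absent) ids;
# absent ids give all-zero rows and are counted for the caller's warning
sim_rows <- function(sim, ids, cols = NULL) {
  cols <- cols %||% colnames(sim$mat)
  out <- matrix(0, length(ids), length(cols), dimnames = list(ids, cols))
  hit <- ids %in% rownames(sim$mat)
  hitcols <- intersect(cols, colnames(sim$mat))
  if (any(hit) && length(hitcols)) {
    out[ids[hit], hitcols] <- as.matrix(sim$mat[ids[hit], hitcols, drop = FALSE])
  }
  attr(out, "n_missing_rows") <- sum(!hit)
  out
}

# one row of a similarity matrix as a named vector over its columns
sim_row_vec <- function(sim, id) {
  m <- sim_rows(sim, id)
  setNames(m[1, ], colnames(m))
}

#' Tanimoto similarity between two fingerprints
#'
#' Size of the bit-set intersection over the union. Defined as 0 when both
#' fingerprints are empty (no shared chemistry evidence).
#'
#' @param fp_a,fp_b integer vectors of set bit indices.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
tanimoto <- function(fp_a, fp_b) {
  a <- unique(fp_a)
  b <- unique(fp_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Hashed path fingerprints from SMILES strings
#'
#' Computes Open Babel FP2 fingerprints (hashed linear substructures of
#' length 1-7, 1024 bits) via ChemmineR/ChemmineOB.
#'
#' @param smiles named character vector of SMILES strings.
#' @return Named list of integer bit-index vectors, with attribute `nbits`.
#' @export
fingerprint_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("fingerprint_smiles() needs the ChemmineR package")
  }
  if (is.null(names(smiles))) names(smiles) <- paste0("mol", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(smiles)
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  m <- fp@fpma
  out <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] != 0))
  names(out) <- names(smiles)
  attr(out, "nbits") <- ncol(m)
  out
}

# ATC prefix sets at hierarchy levels 1-3 (1 / 3 / 4 characters).
# Codes shorter than a level's width simply contribute no prefix there.
atc_prefixes <- function(codes, width) {
  codes <- codes[nchar(codes) >= width]
  unique(substr(codes, 1, width))
}

#' ATC-hierarchy drug similarity
#'
#' The WHO ATC system is a 5-level drug hierarchy; the top three levels
#' (anatomical, therapeutic, pharmacological) are compared. For every pair
#' of codes the deepest shared level L in 0..3 is found and the similarity
#' is the maximum L/3 over all code pairs, landing in \{0, 1/3, 2/3, 1\}.
#'
#' @param codes_a,codes_b non-empty character vectors of ATC codes
#'   (canonical 7-character form; shorter prefixes tolerated).
#' @return Similarity in \[0, 1\].
#' @examples
#' atc_similarity("N06AB03", "N05AH02") # 1/3: shared anatomical group only
#' @export
atc_similarity <- function(codes_a, codes_b) {
  if (length(codes_a) == 0 || length(codes_b) == 0) {
    abort("ATC similarity requires non-empty code sets")
  }
  widths <- c(1L, 3L, 4L)
  for (level in 3:1) {
    w <- widths[level]
    if (length(intersect(atc_prefixes(codes_a, w), atc_prefixes(codes_b, w)))) {
      return(level / 3)
    }
  }
  0
}

#' Yeast-protein alignment coverage similarity
#'
#' Fraction of the yeast protein aligned to the human protein, keeping only
#' significant alignments (E-value < 0.01) and, among multiple alignments,
#' the largest aligned portion.
#'
#' @param records data frame with columns `aligned_span` and `e_value`.
#' @param yeast_length positive integer, yeast protein length in residues.
#' @param e_cutoff significance threshold on the E-value (default 0.01).
#' @return Similarity in \[0, 1\]; 0 if no alignment survives the filter.
#' @export
sequence_similarity <- function(records, yeast_length, e_cutoff = 0.01) {
  stopifnot(yeast_length > 0)
  if (nrow(records) == 0) return(0)
  assert_cols(records, c("aligned_span", "e_value"), "alignment records")
  if (any(records$aligned_span > yeast_length)) {
    abort("aligned_span exceeds the yeast protein length (corrupt input)")
  }
  keep <- records$e_value < e_cutoff
  if (!any(keep)) return(0)
  max(records$aligned_span[keep]) / yeast_length
}

#' Cross-species domain Jaccard similarity
#'
#' Jaccard index of two protein-domain sets after restricting both to the
#' shared universe of domains observed in at least one protein of each
#' species.
#'
#' @param domains_human,domains_yeast character vectors of domain accessions.
#' @param shared_universe character vector: domains present in both species
#'   corpus-wide (see [shared_domain_universe()]).
#' @return Similarity in \[0, 1\]; 0 if either filtered set is empty.
#' @export
domain_similarity <- function(domains_human, domains_yeast, shared_universe) {
  a <- intersect(unique(domains_human), shared_universe)
  b <- intersect(unique(domains_yeast), shared_universe)
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Domains present in both species
#'
#' @param human_genes,yeast_genes gene tibbles with a `domains` list-column.
#' @return Character vector of domain accessions occurring in at least one
#'   human and at least one yeast protein.
#' @export
shared_domain_universe <- function(human_genes, yeast_genes) {
  intersect(
    unique(unlist(human_genes$domains)),
    unique(unlist(yeast_genes$domains))
  )
}

# sparse 0/1 membership matrix: rows = ids, cols = sorted item universe
membership_matrix <- function(ids, sets, universe = NULL) {
  universe <- universe %||% sort(unique(unlist(sets)))
  lens <- lengths(sets)
  j <- match(unlist(sets), universe)
  keep <- !is.na(j)
  Matrix::sparseMatrix(
    i = rep(seq_along(ids), lens)[keep], j = j[keep], x = 1,
    dims = c(length(ids), length(universe)),
    dimnames = list(ids, universe)
  )
}

#' Drug-drug similarity matrix
#'
#' Builds the square, symmetric drug similarity matrix over a drug table,
#' using either hashed-fingerprint Tanimoto or ATC-hierarchy similarity.
#' Drugs with identical non-empty fingerprints or codes score 1 on the
#' diagonal.
#'
#' @param drugs tibble with `drug_id` plus, for `measure = "chemical"`, a
#'   list-column `fp` of fingerprint bit sets, and for `measure = "atc"`, a
#'   list-column `atc` of ATC code vectors.
#' @param measure `"chemical"` or `"atc"`.
#' @return A [new_pgx_sim()] object (drugs x drugs).
#' @export
drug_similarity_matrix <- function(drugs, measure = c("chemical", "atc")) {
  measure <- match.arg(measure)
  ids <- drugs$drug_id
  if (measure == "chemical") {
    assert_cols(drugs, "fp", "drug table")
    M <- membership_matrix(ids, drugs$fp)
    inter <- as.matrix(Matrix::tcrossprod(M))
    sizes <- Matrix::rowSums(M)
    uni <- outer(sizes, sizes, "+") - inter
    sim <- ifelse(uni > 0, inter / uni, 0)
  } else {
    assert_cols(drugs, "atc", "drug table")
    if (any(lengths(drugs$atc) == 0)) {
      abort("ATC similarity requires non-empty code sets for every drug")
    }
    level <- matrix(0, length(ids), length(ids))
    for (w in c(1L, 3L, 4L)) {
      pref <- lapply(drugs$atc, atc_prefixes, width = w)
      if (all(lengths(pref) == 0)) next
      M <- membership_matrix(ids, pref)
      shared <- as.matrix(Matrix::tcrossprod(M)) > 0
      level <- pmax(level, shared * match(w, c(1L, 3L, 4L)))
    }
    sim <- level / 3
  }
  dimnames(sim) <- list(ids, ids)
  new_pgx_sim(sim, measure)
}

#' Human-to-yeast gene similarity matrix
#'
#' Rows are human genes, columns yeast genes. `"sequence"` uses alignment
#' coverage of the yeast protein ([sequence_similarity()]); `"domain"` uses
#' the cross-species domain Jaccard ([domain_similarity()]).
#'
#' @param human_genes tibble with `gene_id` and a `domains` list-column.
#' @param yeast_genes tibble with `gene_id`, `protein_length`, `domains`.
#' @param alignments tibble with `yeast_gene_id`, `human_gene_id`,
#'   `aligned_span`, `e_value` (required for `measure = "sequence"`).
#' @param measure `"sequence"` or `"domain"`.
#' @param e_cutoff E-value significance threshold (default 0.01).
#' @return A [new_pgx_sim()] object (human genes x yeast genes).
#' @export
gene_similarity_matrix <- function(human_genes, yeast_genes, alignments = NULL,
                                   measure = c("sequence", "domain"),
                                   e_cutoff = 0.01) {
  measure <- match.arg(measure)
  hid <- human_genes$gene_id
  yid <- yeast_genes$gene_id
  if (measure == "sequence") {
    if (is.null(alignments)) abort("sequence similarity needs an alignment table")
    assert_cols(alignments, c("yeast_gene_id", "human_gene_id", "aligned_span", "e_value"),
                "alignment table")
    aln <- alignments |>
      inner_join(select(yeast_genes, gene_id, protein_length),
                 by = c(yeast_gene_id = "gene_id"))
    if (any(aln$aligned_span > aln$protein_length)) {
      abort("aligned_span exceeds the yeast protein length (corrupt input)")
    }
    aln <- aln |>
      filter(.data$e_value < e_cutoff,
             .data$human_gene_id %in% hid) |>
      group_by(.data$human_gene_id, .data$yeast_gene_id) |>
      summarise(score = max(.data$aligned_span) / first(.data$protein_length),
                .groups = "drop")
    mat <- Matrix::sparseMatrix(
      i = match(aln$human_gene_id, hid),
      j = match(aln$yeast_gene_id, yid),
      x = aln$score,
      dims = c(length(hid), length(yid)), dimnames = list(hid, yid)
    )
  } else {
    universe <- shared_domain_universe(human_genes, yeast_genes)
    Mh <- membership_matrix(hid, human_genes$domains, universe)
    My <- membership_matrix(yid, yeast_genes$domains, universe)
    inter <- Matrix::tcrossprod(Mh, My)
    trip <- Matrix::summary(methods::as(inter, "TsparseMatrix"))
    sh <- Matrix::rowSums(Mh)
    sy <- Matrix::rowSums(My)
    score <- trip$x / (sh[trip$i] + sy[trip$j] - trip$x)
    mat <- Matrix::sparseMatrix(
      i = trip$i, j = trip$j, x = score,
      dims = c(length(hid), length(yid)), dimnames = list(hid, yid)
    )
  }
  new_pgx_sim(mat, measure)
}

#' Human-to-human gene similarity (for the human-only baseline)
#'
#' `"domain"` is the plain Jaccard of domain sets (no cross-species filter:
#' both sides are human). `"sequence"` symmetrizes directed alignment
#' coverage by taking the maximum of the two directions; with no
#' human-human alignment table only self-similarity is available. The
#' diagonal is always 1 (a gene is fully similar to itself).
#'
#' @param human_genes tibble with `gene_id`, `domains`, and (for sequence
#'   with alignments) `protein_length`.
#' @param alignments_human optional tibble `query_id`, `subject_id`,
#'   `aligned_span`, `e_value`; span covers the query protein.
#' @param measure `"sequence"` or `"domain"`.
#' @param e_cutoff E-value significance threshold (default 0.01).
#' @return A [new_pgx_sim()] object (human genes x human genes).
#' @export
human_gene_similarity_matrix <- function(human_genes, alignments_human = NULL,
                                         measure = c("sequence", "domain"),
                                         e_cutoff = 0.01) {
  measure <- match.arg(measure)
  hid <- human_genes$gene_id
  if (measure == "domain") {
    M <- membership_matrix(hid, human_genes$domains)
    inter <- Matrix::tcrossprod(M)
    trip <- Matrix::summary(methods::as(inter, "TsparseMatrix"))
    s <- Matrix::rowSums(M)
    score <- trip$x / (s[trip$i] + s[trip$j] - trip$x)
    mat <- Matrix::sparseMatrix(
      i = trip$i, j = trip$j, x = score,
      dims = c(length(hid), length(hid)), dimnames = list(hid, hid)
    )
  } else {
    mat <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(length(hid), length(hid)), dimnames = list(hid, hid)
    )
    if (!is.null(alignments_human) && nrow(alignments_human) > 0) {
      assert_cols(alignments_human, c("query_id", "subject_id", "aligned_span", "e_value"),
                  "human alignment table")
      aln <- alignments_human |>
        inner_join(select(human_genes, gene_id, protein_length),
                   by = c(query_id = "gene_id")) |>
        filter(.data$e_value < e_cutoff, .data$subject_id %in% hid) |>
        group_by(.data$query_id, .data$subject_id) |>
        summarise(score = pmin(1, max(.data$aligned_span) / first(.data$protein_length)),
                  .groups = "drop")
      dir1 <- Matrix::sparseMatrix(
        i = match(aln$query_id, hid), j = match(aln$subject_id, hid),
        x = aln$score, dims = c(length(hid), length(hid)),
        dimnames = list(hid, hid)
      )
      dir2 <- Matrix::t(dir1)
      # elementwise max of the two coverage directions, sparse-friendly
      mat <- (dir1 + dir2 + abs(dir1 - dir2)) / 2
    }
  }
  Matrix::diag(mat) <- 1
  new_pgx_sim(mat, measure)
}
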