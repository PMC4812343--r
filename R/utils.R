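# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn inform .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   distinct left_join inner_join anti_join bind_rows bind_cols n row_number
#'   across all_of rename count pull slice desc first
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 map_dbl map_int map_chr map_lgl pmap imap list_rbind keep
#' @importFrom stats rnorm runif rbeta rbinom phyper p.adjust ks.test setNames
#' @importFrom utils head
NULL

# split a semicolon-separated field into a character vector (empty -> chr(0))
split_semi <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_semi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

# max-times product: F[i, j] = max_k A[i, k] * B[k, j].
# The max-plus analogue of %*%; used to push max-of-products through the
# (drug, yeast gene) grid without enumerating triples.
max_times <- function(A, B) {
  stopifnot(ncol(A) == nrow(B))
  out <- matrix(0, nrow(A), ncol(B), dimnames = list(rownames(A), colnames(B)))
  for (k in seq_len(ncol(A))) {
    a <- A[, k]
    if (all(a == 0)) next
    b <- B[k, ]
    if (all(b == 0)) next
    out <- pmax(out, tcrossprod(a, b))
  }
  out
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# derive a child RNG seed from a master seed; keeps values well below 2^31
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
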