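# Synthetic corpus generator. Emulates the flat-file inputs of the real
# pipeline (drug annotations, cross-species homology, HIP/HOP screens,
# gold standard, PPI network) with a planted pharmacogenomic signal so
# every stage is testable without downloads.
#
# Structural assumptions emulated: drugs fall into chemical clusters whose
# members share fingerprint bits and (with probability rising in the
# signal strength) ATC prefixes; a fraction of human genes has a yeast
# homolog with Beta(5,2) alignment coverage and inherited domains; each
# planted positive (D, G) deposits a strong chemogenomic response between
# a screened cluster-mate of D and the yeast homolog of G, on top of
# Gaussian background noise. Positives are drawn uniformly over the
# drug x gene grid (signal is planted only when the gene has a homolog),
# so homology rates in positives and background match and a label-free
# null stays at AUC 0.5. The real screens' score shapes (log-ratio vs
# MADL vs FD-score) are not imitated; scores are opaque reals here.

#' Simulation configuration
#'
#' Defaults are the corpus used throughout the package's self-tests:
#' 200 drugs x 500 human genes x 300 yeast genes, 200 planted positives,
#' 3 screen sources, signal strength 0.9, noise SD 0.1.
#'
#' @param n_drugs,n_human_genes,n_yeast_genes corpus dimensions.
#' @param n_positives number of planted positive pairs.
#' @param n_datasets number of chemogenomic screen sources (default 3).
#' @param signal_strength s in \[0, 1\]: planted raw CGI scores are drawn
#'   from N(s, noise_sd) and cluster-mates share ATC codes with
#'   probability s.
#' @param noise_sd background raw-score SD (>= 0).
#' @param homology_fraction fraction of human genes with a yeast homolog.
#' @param seed master seed; every artifact derives its own stream from it.
#' @param n_clusters number of chemical drug clusters.
#' @param n_screened drugs screened per source.
#' @param nbits fingerprint hash-space size for the random fingerprints.
#' @param n_domains size of the shared (cross-species) domain pool.
#' @param ppi_gene_fraction fraction of human genes present in the PPI
#'   network.
#' @param ppi_degree mean background PPI degree.
#' @return A validated `pgx_sim_config` list.
#' @export
simulation_config <- function(n_drugs = 200, n_human_genes = 500, n_yeast_genes = 300,
                              n_positives = 200, n_datasets = 3,
                              signal_strength = 0.9, noise_sd = 0.1,
                              homology_fraction = 0.9, seed = 1,
                              n_clusters = 40, n_screened = 60, nbits = 512,
                              n_domains = 120, ppi_gene_fraction = 0.7,
                              ppi_degree = 4) {
  cfg <- list(
    n_drugs = n_drugs, n_human_genes = n_human_genes,
    n_yeast_genes = n_yeast_genes, n_positives = n_positives,
    n_datasets = n_datasets, signal_strength = signal_strength,
    noise_sd = noise_sd, homology_fraction = homology_fraction, seed = seed,
    n_clusters = n_clusters, n_screened = n_screened, nbits = nbits,
    n_domains = n_domains, ppi_gene_fraction = ppi_gene_fraction,
    ppi_degree = ppi_degree
  )
  with(cfg, {
    stopifnot(
      n_positives <= n_drugs * n_human_genes,
      signal_strength >= 0, signal_strength <= 1,
      noise_sd >= 0,
      homology_fraction >= 0, homology_fraction <= 1,
      ppi_gene_fraction >= 0, ppi_gene_fraction <= 1,
      n_datasets >= 1, n_clusters >= 1, n_screened >= 1
    )
  })
  if (cfg$homology_fraction * cfg$n_human_genes < 1) {
    abort("homology_fraction * n_human_genes < 1: no transferable signal possible")
  }
  structure(cfg, class = "pgx_sim_config")
}

# toy 3-level ATC hierarchy: 5 anatomical x 4 therapeutic x 3
# pharmacological branches; small enough that the level-based similarity
# takes each of {0, 1/3, 2/3, 1} with non-trivial frequency
toy_atc_code <- function(n) {
  paste0(
    sample(c("A", "B", "C", "D", "N"), n, replace = TRUE),
    sprintf("%02d", sample.int(4, n, replace = TRUE)),
    sample(c("A", "B", "C"), n, replace = TRUE),
    "A", sprintf("%02d", sample.int(99, n, replace = TRUE))
  )
}

random_smiles <- function(n) {
  vapply(seq_len(n), function(i) {
    len <- sample(4:10, 1)
    paste0("C", paste(sample(c("C", "C", "C", "O", "N"), len, replace = TRUE),
                      collapse = ""))
  }, character(1))
}

#' Generate a complete synthetic corpus
#'
#' Deterministic given the configuration: each artifact (drugs,
#' fingerprints, ATC codes, homology, gold standard, screens, PPI,
#' targets) draws from its own RNG stream derived from the master seed, so
#' changing one component's parameters does not perturb the others.
#'
#' @param cfg a [simulation_config()].
#' @return A `pgx_corpus`: list with `drugs`, `human_genes`,
#'   `yeast_genes`, `alignments`, `alignments_human`, `gold`, `cgi`
#'   (prepared datasets), `cgi_scores`/`cgi_conditions` (condition-level
#'   flat tables), `ppi`, `targets`, and `config`.
#' @export
generate_corpus <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "pgx_sim_config"))
  seed <- cfg$seed

  # --- drugs: clusters, fingerprints, ATC codes, SMILES -------------------
  drug_ids <- sprintf("D%04d", seq_len(cfg$n_drugs))
  cluster <- withr::with_seed(child_seed(seed, 1L), {
    sample.int(cfg$n_clusters, cfg$n_drugs, replace = TRUE)
  })
  fp <- withr::with_seed(child_seed(seed, 2L), {
    core <- map(seq_len(cfg$n_clusters), function(i) sample.int(cfg$nbits, 40))
    map(seq_len(cfg$n_drugs), function(i) {
      keep <- core[[cluster[i]]][runif(40) < 0.8]
      sort(unique(c(keep, sample.int(cfg$nbits, 15))))
    })
  })
  atc <- withr::with_seed(child_seed(seed, 3L), {
    home <- toy_atc_code(cfg$n_clusters)
    map(seq_len(cfg$n_drugs), function(i) {
      code <- if (runif(1) < cfg$signal_strength) {
        paste0(substr(home[cluster[i]], 1, 4), "A", sprintf("%02d", sample.int(99, 1)))
      } else {
        toy_atc_code(1)
      }
      if (runif(1) < 0.2) c(code, toy_atc_code(1)) else code
    })
  })
  smiles <- withr::with_seed(child_seed(seed, 4L), random_smiles(cfg$n_drugs))
  drugs <- tibble(
    drug_id = drug_ids, smiles = smiles, atc = atc, fp = fp,
    nbits = cfg$nbits, cluster = cluster
  )

  # --- genes, homology, domains, alignments -------------------------------
  hh <- withr::with_seed(child_seed(seed, 5L), {
    yeast_ids <- sprintf("Y%04d", seq_len(cfg$n_yeast_genes))
    human_ids <- sprintf("HG%04d", seq_len(cfg$n_human_genes))
    shared_pool <- sprintf("PF%04d", seq_len(cfg$n_domains))
    human_pool <- sprintf("HD%04d", seq_len(max(40, cfg$n_domains %/% 3)))
    yeast <- tibble(
      gene_id = yeast_ids,
      protein_length = sample(200:1200, cfg$n_yeast_genes, replace = TRUE),
      domains = map(seq_len(cfg$n_yeast_genes), function(i) {
        sort(sample(shared_pool, sample(1:4, 1)))
      })
    )
    n_homolog <- floor(cfg$homology_fraction * cfg$n_human_genes)
    homolog_idx <- sort(sample.int(cfg$n_human_genes, n_homolog))
    partner <- setNames(rep(NA_character_, cfg$n_human_genes), human_ids)
    partner[homolog_idx] <- sample(yeast_ids, n_homolog, replace = TRUE)
    human <- tibble(
      gene_id = human_ids,
      protein_length = sample(200:1200, cfg$n_human_genes, replace = TRUE),
      domains = map(seq_len(cfg$n_human_genes), function(i) {
        if (!is.na(partner[i])) {
          inherited <- yeast$domains[[match(partner[i], yeast_ids)]]
          inherited <- inherited[runif(length(inherited)) < 0.85]
          extra <- if (runif(1) < 0.3) sample(human_pool, 1) else character(0)
          sort(unique(c(inherited, extra)))
        } else {
          own <- sample(human_pool, sample(1:3, 1))
          noise <- if (runif(1) < 0.15) sample(shared_pool, 1) else character(0)
          sort(unique(c(own, noise)))
        }
      })
    )
    ylen <- setNames(yeast$protein_length, yeast_ids)
    hom <- tibble(
      human_gene_id = human_ids[homolog_idx],
      yeast_gene_id = partner[homolog_idx],
      coverage = rbeta(n_homolog, 5, 2)
    ) |>
      mutate(
        aligned_span = pmax(1, round(.data$coverage * ylen[.data$yeast_gene_id])),
        e_value = 10^-runif(n_homolog, 4, 80)
      )
    n_decoy <- round(0.1 * cfg$n_human_genes)
    decoy <- tibble(
      human_gene_id = sample(human_ids, n_decoy, replace = TRUE),
      yeast_gene_id = sample(yeast_ids, n_decoy, replace = TRUE)
    ) |>
      mutate(
        aligned_span = pmax(1, round(runif(n_decoy, 0.1, 0.9) *
                                       ylen[.data$yeast_gene_id])),
        e_value = runif(n_decoy, 0.02, 2)
      )
    alignments <- bind_rows(
      select(hom, "yeast_gene_id", "human_gene_id", "aligned_span", "e_value"),
      select(decoy, "yeast_gene_id", "human_gene_id", "aligned_span", "e_value")
    )
    # paralog pairs: human genes sharing a yeast partner align to each other
    hlen <- setNames(human$protein_length, human_ids)
    groups <- split(human_ids[homolog_idx], partner[homolog_idx])
    para <- list_rbind(map(keep(groups, function(g) length(g) >= 2), function(g) {
      cmb <- utils::combn(g, 2)
      tibble(query_id = c(cmb[1, ], cmb[2, ]), subject_id = c(cmb[2, ], cmb[1, ]))
    }))
    alignments_human <- if (nrow(para)) {
      para |> mutate(
        aligned_span = pmax(1, round(rbeta(n(), 5, 2) * hlen[.data$query_id])),
        e_value = 10^-runif(n(), 4, 40)
      )
    } else {
      tibble(query_id = character(0), subject_id = character(0),
             aligned_span = integer(0), e_value = numeric(0))
    }
    list(yeast = yeast, human = human, partner = partner,
         alignments = alignments, alignments_human = alignments_human)
  })

  # --- gold standard: planted positives, some expressed via drug classes --
  gold_tabs <- withr::with_seed(child_seed(seed, 6L), {
    idx <- sample.int(cfg$n_drugs * cfg$n_human_genes, cfg$n_positives)
    pos <- tibble(
      drug_id = drug_ids[(idx - 1L) %% cfg$n_drugs + 1L],
      gene_id = hh$human$gene_id[(idx - 1L) %/% cfg$n_drugs + 1L]
    )
    by_gene <- split(pos$drug_id, pos$gene_id)
    class_genes <- names(keep(by_gene, function(d) length(d) >= 2))
    class_genes <- class_genes[runif(length(class_genes)) < 0.5]
    class_records <- tibble(
      class_id = sprintf("CL%03d", seq_along(class_genes)),
      gene_id = class_genes
    )
    class_members <- list_rbind(imap(setNames(class_genes, class_records$class_id),
      function(g, cid) tibble(class_id = cid, drug_id = by_gene[[g]])
    ))
    direct <- anti_join(pos, class_records, by = "gene_id")
    list(positives = pos, direct = direct,
         class_records = class_records,
         class_members = class_members %||%
           tibble(class_id = character(0), drug_id = character(0)))
  })
  positives <- gold_tabs$positives

  # --- chemogenomic screens ----------------------------------------------
  sources <- paste0("screen_", letters[seq_len(cfg$n_datasets)])
  cgi_tabs <- withr::with_seed(child_seed(seed, 7L), {
    yeast_ids <- hh$yeast$gene_id
    all_scores <- list()
    all_conditions <- list()
    for (src in sources) {
      # screened drugs cover the chemical clusters, then fill at random
      pick_per_cluster <- map_chr(sample(seq_len(cfg$n_clusters)), function(cl) {
        members <- drug_ids[cluster == cl]
        if (length(members)) sample(members, 1) else NA_character_
      })
      screened <- head(pick_per_cluster[!is.na(pick_per_cluster)], cfg$n_screened)
      if (length(screened) < cfg$n_screened) {
        screened <- c(screened, sample(setdiff(drug_ids, screened),
                                       cfg$n_screened - length(screened)))
      }
      for (assay in c("HIP", "HOP")) {
        raw <- matrix(
          rnorm(cfg$n_yeast_genes * length(screened), 0, cfg$noise_sd),
          cfg$n_yeast_genes, length(screened),
          dimnames = list(yeast_ids, screened)
        )
        for (i in seq_len(nrow(positives))) {
          g <- hh$partner[positives$gene_id[i]]
          if (is.na(g)) next # gene without a yeast homolog: no signal
          mates <- screened[cluster[match(screened, drug_ids)] ==
                              cluster[match(positives$drug_id[i], drug_ids)]]
          d <- if (length(mates)) mates[1] else next
          raw[g, d] <- rnorm(1, cfg$signal_strength, cfg$noise_sd)
        }
        conds <- list_rbind(map(seq_along(screened), function(j) {
          n_cond <- sample(1:2, 1)
          conc <- sample(c(10, 25, 50, 100), n_cond)
          tibble(
            condition_id = sprintf("%s_%s_%s_c%d", src, tolower(assay),
                                   screened[j], seq_len(n_cond)),
            drug_id = screened[j], concentration = conc,
            assay = assay, source = src
          )
        }))
        top <- conds |> group_by(.data$drug_id) |>
          arrange(desc(.data$concentration), .data$condition_id, .by_group = TRUE) |>
          slice(1) |> ungroup()
        scores <- list_rbind(map(seq_len(nrow(conds)), function(r) {
          d <- conds$drug_id[r]
          is_top <- conds$condition_id[r] %in% top$condition_id
          v <- if (is_top) raw[, d] else {
            0.5 * raw[, d] + rnorm(cfg$n_yeast_genes, 0, cfg$noise_sd / 2)
          }
          tibble(yeast_gene_id = yeast_ids, condition_id = conds$condition_id[r],
                 raw_score = unname(v))
        }))
        all_scores[[paste(src, assay)]] <- scores
        all_conditions[[paste(src, assay)]] <- conds
      }
    }
    list(scores = list_rbind(all_scores), conditions = list_rbind(all_conditions))
  })
  cgi <- suppressMessages(prepare_cgi(cgi_tabs$scores, cgi_tabs$conditions,
                                      drug_ids = drug_ids))

  # --- PPI network --------------------------------------------------------
  ppi <- withr::with_seed(child_seed(seed, 8L), {
    net_genes <- sort(sample(hh$human$gene_id,
                             round(cfg$ppi_gene_fraction * cfg$n_human_genes)))
    by_drug <- split(positives$gene_id, positives$drug_id)
    cohit <- list_rbind(map(keep(by_drug, function(g) length(g) >= 2), function(g) {
      g <- intersect(g, net_genes)
      if (length(g) < 2) return(NULL)
      cmb <- utils::combn(sort(g), 2)
      tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
    }))
    if (!is.null(cohit) && nrow(cohit)) {
      cohit <- cohit[runif(nrow(cohit)) < 0.6, ]
    }
    n_bg <- round(cfg$ppi_degree * length(net_genes) / 2)
    bg <- tibble(
      gene_a = sample(net_genes, n_bg, replace = TRUE),
      gene_b = sample(net_genes, n_bg, replace = TRUE)
    )
    bind_rows(cohit, bg) |>
      filter(.data$gene_a != .data$gene_b) |>
      mutate(
        lo = pmin(.data$gene_a, .data$gene_b),
        hi = pmax(.data$gene_a, .data$gene_b)
      ) |>
      distinct(.data$lo, .data$hi) |>
      rename(gene_a = "lo", gene_b = "hi")
  })

  # --- drug-target associations (for the PPI baseline) --------------------
  targets <- withr::with_seed(child_seed(seed, 9L), {
    from_pos <- positives[sample.int(nrow(positives), round(0.3 * nrow(positives))), ]
    n_rand <- round(0.2 * cfg$n_positives)
    rand <- tibble(
      drug_id = sample(drug_ids, n_rand, replace = TRUE),
      gene_id = sample(hh$human$gene_id, n_rand, replace = TRUE)
    )
    distinct(bind_rows(from_pos, rand), .data$drug_id, .data$gene_id)
  })

  gold <- structure(
    list(
      pairs = positives, direct = gold_tabs$direct,
      class_records = gold_tabs$class_records,
      class_members = gold_tabs$class_members
    ),
    class = "pgx_gold"
  )

  structure(
    list(
      drugs = drugs, human_genes = hh$human, yeast_genes = hh$yeast,
      alignments = hh$alignments, alignments_human = hh$alignments_human,
      gold = gold, cgi = cgi,
      cgi_scores = cgi_tabs$scores, cgi_conditions = cgi_tabs$conditions,
      ppi = ppi, targets = targets, config = cfg
    ),
    class = "pgx_corpus"
  )
}

#' @export
print.pgx_corpus <- function(x, ...) {
  cat(sprintf(
    "<pgx_corpus> %d drugs, %d human genes, %d yeast genes, %d positives, %d screens\n",
    nrow(x$drugs), nrow(x$human_genes), nrow(x$yeast_genes),
    nrow(x$gold$pairs), length(x$cgi)
  ))
  invisible(x)
}

#' Build all four similarity matrices of a corpus
#'
#' @param corpus a [generate_corpus()] result (or any corpus bundle with
#'   the same components).
#' @return List with `drug = list(chemical, atc)` and
#'   `gene = list(sequence, domain)` similarity matrices.
#' @export
corpus_similarities <- function(corpus) {
  list(
    drug = list(
      chemical = drug_similarity_matrix(corpus$drugs, "chemical"),
      atc = drug_similarity_matrix(corpus$drugs, "atc")
    ),
    gene = list(
      sequence = gene_similarity_matrix(corpus$human_genes, corpus$yeast_genes,
                                        corpus$alignments, "sequence"),
      domain = gene_similarity_matrix(corpus$human_genes, corpus$yeast_genes,
                                      measure = "domain")
    )
  )
}

#' Human-human similarity matrices of a corpus (baseline inputs)
#'
#' @param corpus a corpus bundle.
#' @return List with `sequence` and `domain` human x human matrices.
#' @export
corpus_human_similarities <- function(corpus) {
  list(
    sequence = human_gene_similarity_matrix(corpus$human_genes,
                                            corpus$alignments_human, "sequence"),
    domain = human_gene_similarity_matrix(corpus$human_genes, measure = "domain")
  )
}

#' Destroy the drug-gene linkage of the chemogenomic screens
#'
#' Permutes the yeast-gene labels of every prepared chemogenomic dataset,
#' independently per dataset. Row score multisets are preserved, so all
#' marginal distributions survive while the planted signal is destroyed —
#' the negative control for signal-dependence tests.
#'
#' @param corpus a `pgx_corpus`.
#' @param seed integer seed.
#' @return The corpus with shuffled `cgi` datasets.
#' @export
shuffle_cgi_null <- function(corpus, seed = 1) {
  corpus$cgi <- imap(corpus$cgi, function(ds, nm) {
    genes <- sort(unique(ds$scores$yeast_gene_id))
    perm <- withr::with_seed(child_seed(seed, match(nm, names(corpus$cgi))), {
      setNames(sample(genes), genes)
    })
    ds$scores$yeast_gene_id <- unname(perm[ds$scores$yeast_gene_id])
    ds
  })
  corpus
}
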