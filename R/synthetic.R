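# Synthetic interactome, expression and gene-set generators. These stand
# in for database downloads: they emit the exact dialects the readers
# consume, with the statistical structure the analysis assumes (heavy-
# tailed degrees, incomplete tissue coverage, planted shared partners and
# a planted over-represented term), all reproducible from one seed.

#' Configuration for the synthetic generators
#'
#' Defaults mirror the study conditions of the seed-gene interactome
#' analysis: 4 RTT and 58 RTT-L seed genes, a 2254-protein interactome
#' (so the seeds sit among ~2192 potential neighbors), 63 planted common
#' interactors shared between the two seed classes, and a brain expression
#' table in which a modest fraction of proteins is not detected or has no
#' record at all.
#'
#' @param n_nodes total proteins (seeds + interactors), `>= 10`.
#' @param attachment_m preferential-attachment edges per new node.
#' @param n_rtt_seeds,n_rttl_seeds seed counts (ignored when a catalog is
#'   passed to [generate_interactome()]).
#' @param tissue tissue name for expression records.
#' @param p_not_detected probability a covered protein is called
#'   `not_detected` in the tissue.
#' @param p_uncovered probability a protein has no expression record.
#' @param planted_common_k interactors wired to at least one seed of each
#'   class; the construction guarantees the common-interactor count equals
#'   this exactly.
#' @param n_seed_seed_edges direct seed-seed edges to add (cross-talk).
#' @param partner_meanlog,partner_sdlog log-normal parameters for the
#'   per-seed partner count (heavy-tailed seed degrees).
#' @param n_terms random gene-set terms besides the planted one.
#' @param term_size_range inclusive size bounds for random terms.
#' @param planted_term_K,planted_term_k planted term size and its overlap
#'   with the designated query set.
#' @param rng_seed integer seed; every generator derives its stream from
#'   it, so identical configurations reproduce identical files.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 2254, attachment_m = 2,
                             n_rtt_seeds = 4, n_rttl_seeds = 58,
                             tissue = "brain", p_not_detected = 0.15,
                             p_uncovered = 0.05, planted_common_k = 63,
                             n_seed_seed_edges = 2,
                             partner_meanlog = log(20), partner_sdlog = 1,
                             n_terms = 50, term_size_range = c(10, 50),
                             planted_term_K = 20, planted_term_k = 15,
                             rng_seed = 1) {
  stopifnot(
    n_nodes >= 10, attachment_m >= 1,
    n_rtt_seeds >= 0, n_rttl_seeds >= 0,
    n_rtt_seeds + n_rttl_seeds >= 1,
    n_rtt_seeds + n_rttl_seeds < n_nodes,
    p_not_detected >= 0, p_not_detected <= 1,
    p_uncovered >= 0, p_uncovered <= 1,
    planted_common_k >= 0,
    planted_term_k <= planted_term_K,
    length(term_size_range) == 2, term_size_range[1] <= term_size_range[2]
  )
  structure(
    list(n_nodes = n_nodes, attachment_m = attachment_m,
         n_rtt_seeds = n_rtt_seeds, n_rttl_seeds = n_rttl_seeds,
         tissue = tissue, p_not_detected = p_not_detected,
         p_uncovered = p_uncovered, planted_common_k = planted_common_k,
         n_seed_seed_edges = n_seed_seed_edges,
         partner_meanlog = partner_meanlog, partner_sdlog = partner_sdlog,
         n_terms = n_terms, term_size_range = term_size_range,
         planted_term_K = planted_term_K, planted_term_k = planted_term_k,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic interactome
#'
#' Builds a preferential-attachment backbone over the interactor proteins
#' (connected, heavy-tailed degrees), then wires each seed to a
#' class-reserved partner pool with degree-biased, log-normally sized
#' neighborhoods, plants exactly `planted_common_k` interactors adjacent
#' to at least one seed of each class (every other interactor is wired to
#' one class only, so the common-interactor count is exact by
#' construction), and adds a few direct seed-seed edges. Planting adds
#' edges rather than rewiring, so the backbone's degree structure is kept
#' (planted nodes gain degree). All edges are `experimental`.
#'
#' @param config a [synthetic_config()].
#' @param catalog optional `gene_catalog` whose symbols become the seeds;
#'   when `NULL`, generic seeds `RTT01..`/`RTTL01..` are generated along
#'   with a matching catalog.
#' @return list with `edges` (an `interaction_edges` data.frame) and
#'   `catalog` (the seed `gene_catalog` used).
#' @export
generate_interactome <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(catalog)) {
    recs <- data.frame(symbol = character(0), gene_class = character(0),
                       provenance = character(0), stringsAsFactors = FALSE)
    if (config$n_rtt_seeds > 0) {
      recs <- rbind(recs, data.frame(
        symbol = sprintf("RTT%02d", seq_len(config$n_rtt_seeds)),
        gene_class = "RTT_CLASSICAL", provenance = "synthetic"))
    }
    if (config$n_rttl_seeds > 0) {
      recs <- rbind(recs, data.frame(
        symbol = sprintf("RTTL%02d", seq_len(config$n_rttl_seeds)),
        gene_class = "RTTL_LITERATURE", provenance = "synthetic"))
    }
    catalog <- new_gene_catalog(recs)
  }
  rtt <- rtt_symbols(catalog)
  rttl <- setdiff(rttl_symbols(catalog), rtt) # wiring follows class precedence
  n_int <- config$n_nodes - length(rtt) - length(rttl)
  if (n_int < 2) fail("n_nodes leaves fewer than 2 interactors")
  have_both <- length(rtt) > 0 && length(rttl) > 0
  if (config$planted_common_k > 0 && !have_both) {
    fail("planting common interactors needs seeds of both classes")
  }
  n_reserved <- config$planted_common_k +
    (length(rtt) > 0) + (length(rttl) > 0)
  if (n_int < n_reserved) {
    fail("infeasible planting: ", n_int, " interactors cannot host ",
         config$planted_common_k, " common partners plus class pools")
  }

  with_seed(config$rng_seed, {
    ints <- sprintf("GENE%05d", seq_len(n_int))
    backbone <- igraph::sample_pa(n_int, power = 1, m = config$attachment_m,
                                  directed = FALSE)
    bedges <- igraph::as_edgelist(backbone, names = FALSE)
    bdeg <- igraph::degree(backbone)
    edge_a <- ints[bedges[, 1]]
    edge_b <- ints[bedges[, 2]]

    common <- sample(ints, config$planted_common_k)
    rest <- setdiff(ints, common)
    n_pool_rtt <- if (length(rtt) == 0) 0 else if (length(rttl) == 0) length(rest) else
      max(1, round(length(rest) * length(rtt) / (length(rtt) + length(rttl))))
    pool_rtt <- if (n_pool_rtt > 0) sample(rest, n_pool_rtt) else character(0)
    pool_rttl <- setdiff(rest, pool_rtt)
    if (length(rttl) > 0 && length(pool_rttl) == 0) fail("empty RTT-L partner pool")

    wire_class <- function(seeds, pool) {
      if (!length(seeds) || !length(pool)) return(NULL)
      w <- bdeg[match(pool, ints)] + 1
      do.call(rbind, lapply(seeds, function(s) {
        npart <- max(1L, min(length(pool),
                             round(stats::rlnorm(1, config$partner_meanlog,
                                                 config$partner_sdlog))))
        data.frame(a = s, b = sample(pool, npart, prob = w),
                   stringsAsFactors = FALSE)
      }))
    }
    wires <- rbind(wire_class(rtt, pool_rtt), wire_class(rttl, pool_rttl))
    planted <- if (config$planted_common_k > 0) {
      data.frame(
        a = c(sample(rtt, config$planted_common_k, replace = TRUE),
              sample(rttl, config$planted_common_k, replace = TRUE)),
        b = c(common, common), stringsAsFactors = FALSE
      )
    } else NULL
    seeds_all <- c(rtt, rttl)
    seed_seed <- if (config$n_seed_seed_edges > 0 && length(seeds_all) >= 2) {
      do.call(rbind, lapply(seq_len(config$n_seed_seed_edges), function(i) {
        pair <- sample(seeds_all, 2)
        data.frame(a = pair[1], b = pair[2], stringsAsFactors = FALSE)
      }))
    } else NULL

    all_a <- c(edge_a, wires$a, planted$a, seed_seed$a)
    all_b <- c(edge_b, wires$b, planted$b, seed_seed$b)
    df <- data.frame(
      symbol_a = pmin(all_a, all_b), symbol_b = pmax(all_a, all_b),
      evidence = "experimental", sources = "synthetic", tissues = "",
      stringsAsFactors = FALSE
    )
    list(edges = canonical_edges(df), catalog = catalog)
  })
}

#' Generate a synthetic protein expression table
#'
#' Each symbol is independently uncovered (no record at all) with
#' probability `p_uncovered`; otherwise it gets one record for the
#' configured tissue: `not_detected` with probability `p_not_detected`,
#' else a level drawn uniformly from low/medium/high. Forcing a seed to be
#' uncovered reproduces the CDKL5 situation, where missing protein-level
#' evidence removes a seed from the tissue network.
#'
#' @param config a [synthetic_config()].
#' @param symbols symbols to cover.
#' @param force_uncovered symbols guaranteed to have no record.
#' @return an `expression_table`.
#' @export
generate_expression <- function(config, symbols, force_uncovered = NULL) {
  stopifnot(inherits(config, "synthetic_config"), length(symbols) > 0)
  symbols <- unique(normalize_symbol(symbols))
  with_seed(config$rng_seed + 1L, {
    covered <- stats::runif(length(symbols)) >= config$p_uncovered
    covered[symbols %in% normalize_symbol(force_uncovered)] <- FALSE
    syms <- symbols[covered]
    nd <- stats::runif(length(syms)) < config$p_not_detected
    lvl <- ifelse(nd, "not_detected",
                  sample(c("low", "medium", "high"), length(syms), replace = TRUE))
    out <- data.frame(symbol = syms, tissue = tolower(config$tissue),
                      level = lvl, stringsAsFactors = FALSE)
    out <- out[order(out$symbol), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("expression_table", "data.frame")
    out
  })
}

#' Generate a synthetic gene-set collection with one planted term
#'
#' The planted term has size `planted_term_K` with exactly
#' `planted_term_k` members drawn from the designated query set; the
#' remaining terms are drawn uniformly from the universe within the
#' configured size bounds. Used to verify that the enrichment stage
#' recovers a known over-represented term.
#'
#' @param config a [synthetic_config()].
#' @param universe character vector of background symbols.
#' @param query the designated query set the planted term overlaps.
#' @param source annotation source tag for all terms.
#' @return a `term_sets` data.frame; the planted term has
#'   `term_id = "PLANTED"`.
#' @export
generate_gmt <- function(config, universe, query, source = "GO_BP") {
  stopifnot(inherits(config, "synthetic_config"))
  universe <- unique(normalize_symbol(universe))
  query <- intersect(unique(normalize_symbol(query)), universe)
  K <- config$planted_term_K
  k <- config$planted_term_k
  if (K > length(universe)) fail("planted term size exceeds the universe")
  if (k > length(query) || (K - k) > length(universe) - length(query)) {
    fail("infeasible planted term: K=", K, ", k=", k, " given |query|=",
         length(query), ", |universe|=", length(universe))
  }
  with_seed(config$rng_seed + 2L, {
    planted_members <- sort(c(
      sample(query, k),
      sample(setdiff(universe, query), K - k)
    ))
    size_choices <- seq(config$term_size_range[1], config$term_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), config$n_terms,
                                     replace = TRUE)]
    sizes <- pmin(sizes, length(universe))
    members <- lapply(sizes, function(s) sort(sample(universe, s)))
    out <- data.frame(
      term_id = c("PLANTED", sprintf("T%04d", seq_len(config$n_terms))),
      term_name = c("planted over-represented term",
                    sprintf("random term %d", seq_len(config$n_terms))),
      source = source, stringsAsFactors = FALSE
    )
    out$members <- c(list(planted_members), members)
    class(out) <- c("term_sets", "data.frame")
    out
  })
}
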