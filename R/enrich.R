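# Multi-source over-representation analysis: hypergeometric tests with
# Bonferroni correction, and pathway-membership mapping onto the network.

check_hyper_args <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n) ||
      k < max(0, n - (N - K))) {
    fail("invalid hypergeometric arguments: N=", N, " K=", K, " n=", n, " k=", k)
  }
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` query genes are drawn from
#' a universe of `N` genes of which `K` carry the annotation. This is the
#' over-representation direction. Computed through the stable tail routines
#' of [stats::phyper()], never by naive summation of cancelled factorials.
#'
#' @param N universe size.
#' @param K annotated genes in the universe (term size).
#' @param n query size.
#' @param k overlap.
#' @return p-value in `[0, 1]`.
#' @examples
#' hypergeom_upper(10, 5, 4, 4) # 5/210
#' @export
hypergeom_upper <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided hypergeometric p-value (minimum-likelihood method)
#'
#' Sums the probabilities of all outcomes whose point probability does not
#' exceed that of the observed overlap `k` (within a small relative
#' tolerance to absorb floating-point ties), capped at 1. When `k` is the
#' largest achievable overlap this reduces to the upper tail.
#'
#' @inheritParams hypergeom_upper
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_two_sided <- function(N, K, n, k) {
  check_hyper_args(N, K, n, k)
  support <- max(0, n - (N - K)):min(n, K)
  logp <- stats::dhyper(support, K, N - K, n, log = TRUE)
  cutoff <- stats::dhyper(k, K, N - K, n, log = TRUE)
  min(1, sum(exp(logp[logp <= cutoff + 1e-7])))
}

#' Multi-source over-representation analysis
#'
#' For every annotation term, tests whether the query gene set overlaps the
#' term more than expected under hypergeometric sampling from the
#' background universe, then applies a Bonferroni correction. The
#' correction scope defaults to per-source (each annotation database
#' corrected by its own term count, the g:Profiler convention);
#' `correction_scope = "global"` corrects by the total across sources.
#' Terms with zero query overlap count toward the correction burden `m`
#' but are excluded from the output; terms with no background members are
#' untestable and ignored entirely.
#'
#' @param query character vector of query gene symbols.
#' @param sources a `term_sets` data.frame ([read_gmt()]), or a list of
#'   them (rows are concatenated; `source` tags distinguish them).
#' @param background universe of symbols. Default `NULL` uses the union of
#'   all member symbols across the loaded sources; alternatives are any
#'   user-supplied vector (e.g. the network's node symbols). The query is
#'   restricted to the background before testing.
#' @param alpha significance level for the `significant` flag (default
#'   0.05, applied to the corrected p-value).
#' @param sidedness `"upper"` (over-representation, default) or
#'   `"two_sided"` (minimum-likelihood two-sided test).
#' @param correction_scope `"per_source"` or `"global"`.
#' @return data.frame of class `enrichment_result`, sorted by `p_adj` then
#'   `term_id`: `term_id`, `term_name`, `source`, `K`, `n`, `k`, `p_raw`,
#'   `p_adj`, `significant`, list-column `overlap`. Attributes: `m`
#'   (named per-source test counts), `n_universe`, `n_query`.
#' @export
run_enrichment <- function(query, sources, background = NULL, alpha = 0.05,
                           sidedness = c("upper", "two_sided"),
                           correction_scope = c("per_source", "global")) {
  sidedness <- match.arg(sidedness)
  correction_scope <- match.arg(correction_scope)
  stopifnot(alpha > 0, alpha < 1)
  if (is.list(sources) && !inherits(sources, "data.frame")) {
    sources <- do.call(rbind, lapply(sources, as.data.frame))
    class(sources) <- c("term_sets", "data.frame")
  }
  stopifnot(inherits(sources, "term_sets"))
  if (anyDuplicated(paste(sources$source, sources$term_id))) {
    fail("duplicate term_id within a source")
  }
  query <- unique(normalize_symbol(query))
  background <- if (is.null(background)) {
    sort(unique(unlist(sources$members)))
  } else {
    sort(unique(normalize_symbol(background)))
  }
  query <- intersect(query, background)
  if (!length(query)) fail("query is empty after restriction to the background")
  N <- length(background)
  n <- length(query)

  members_bg <- lapply(sources$members, intersect, background)
  Ks <- lengths(members_bg)
  testable <- Ks >= 1
  m_by_source <- tapply(testable, sources$source, sum)
  m_for <- function(src) {
    if (correction_scope == "global") sum(testable) else m_by_source[[src]]
  }

  overlaps <- lapply(members_bg, intersect, query)
  ks <- lengths(overlaps)
  keep <- testable & ks >= 1
  pfun <- if (sidedness == "upper") hypergeom_upper else hypergeom_two_sided
  idx <- which(keep)
  p_raw <- vapply(idx, function(i) pfun(N, Ks[[i]], n, ks[[i]]), numeric(1))
  p_adj <- vapply(seq_along(idx), function(j) {
    min(1, m_for(sources$source[[idx[[j]]]]) * p_raw[[j]])
  }, numeric(1))

  out <- data.frame(
    term_id = sources$term_id[idx],
    term_name = sources$term_name[idx],
    source = sources$source[idx],
    K = as.integer(Ks[idx]), n = rep(n, length(idx)),
    k = as.integer(ks[idx]),
    p_raw = p_raw, p_adj = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE
  )
  out$overlap <- overlaps[idx]
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m_by_source
  attr(out, "n_universe") <- N
  attr(out, "n_query") <- n
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Export enrichment results as TSV
#' @param result an `enrichment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  df <- as.data.frame(result)
  df$overlap <- vapply(df$overlap, paste, character(1), collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a pathway's membership onto the network
#'
#' Reports which seed genes of each class belong to the pathway, and which
#' pathway members are simultaneously common interactors of both seed
#' classes in the network — the proteins that sit inside the pathway *and*
#' bridge the RTT and RTT-L neighborhoods.
#'
#' @param network a classified `ppin`.
#' @param catalog the seed `gene_catalog`.
#' @param pathway a single-row `term_sets` slice, or a character vector of
#'   pathway member symbols.
#' @param term_id identifier recorded in the result (taken from `pathway`
#'   when it is a `term_sets` row).
#' @return list of class `pathway_map`: `term_id`, `members`,
#'   `rtt_members`, `rttl_members`, `shared_interactors`, and the three
#'   counts `n_rtt`, `n_rttl`, `n_shared`.
#' @export
map_pathway <- function(network, catalog, pathway, term_id = "pathway") {
  if (inherits(pathway, "term_sets") || is.data.frame(pathway)) {
    stopifnot(nrow(pathway) == 1)
    term_id <- pathway$term_id[[1]]
    members <- pathway$members[[1]]
  } else {
    members <- unique(normalize_symbol(pathway))
  }
  if (!length(members)) fail("pathway has no members")
  rtt_m <- sort(intersect(members, rtt_symbols(catalog)))
  rttl_m <- sort(intersect(setdiff(members, rtt_symbols(catalog)), rttl_symbols(catalog)))
  shared <- sort(intersect(members, common_interactors(network)$common))
  structure(
    list(term_id = term_id, members = sort(members),
         rtt_members = rtt_m, rttl_members = rttl_m,
         shared_interactors = shared,
         n_rtt = length(rtt_m), n_rttl = length(rttl_m),
         n_shared = length(shared)),
    class = "pathway_map"
  )
}

#' @export
print.pathway_map <- function(x, ...) {
  cat("Pathway map:", x$term_id, "(", length(x$members), "members )\n")
  cat("  RTT seed members:  ", x$n_rtt, "\n")
  cat("  RTT-L seed members:", x$n_rttl, "\n")
  cat("  shared interactors:", paste(x$shared_interactors, collapse = ", "), "\n")
  invisible(x)
}
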