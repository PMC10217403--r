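# Tissue restriction of the PPIN by the protein-expression rule, and
# class-specific partner sets with their intersection.

#' Is a protein expressed in a tissue?
#'
#' A protein counts as expressed in a tissue when it has an expression
#' record for that tissue at any level other than `not_detected`. A symbol
#' with no record for the tissue is treated as not expressed: absence of
#' protein-level evidence removes the node, which is exactly how CDKL5
#' drops out of the brain-restricted network.
#'
#' @param symbols character vector of gene symbols (normalized or not).
#' @param tissue tissue name, matched case-insensitively.
#' @param table an `expression_table` from [read_expression()].
#' @return logical vector along `symbols`.
#' @export
expressed <- function(symbols, tissue, table) {
  stopifnot(inherits(table, "expression_table"))
  symbols <- normalize_symbol(symbols)
  tissue <- tolower(trimws(tissue))
  hit <- table$tissue == tissue & table$level != "not_detected"
  symbols %in% table$symbol[hit]
}

# symbols with any record (any level) for the tissue
covered <- function(symbols, tissue, table) {
  tissue <- tolower(trimws(tissue))
  normalize_symbol(symbols) %in% table$symbol[table$tissue == tissue]
}

#' Restrict a network to a tissue
#'
#' Node-expression mode (the default) keeps a node iff [expressed()] holds
#' for it, and keeps an edge iff both endpoints are kept; the result is a
#' subgraph of the input. Edge-flag mode instead keeps an edge iff the
#' interaction record itself is flagged for the tissue (IID-style per-edge
#' tissue annotation), nodes being the retained endpoints.
#'
#' @param network a `ppin`.
#' @param table an `expression_table` (ignored in edge-flag mode).
#' @param tissue tissue name.
#' @param keep_uncovered keep symbols that have no expression record for
#'   the tissue instead of dropping them (default `FALSE`).
#' @param mode `"node"` (expression rule) or `"edge_flag"`.
#' @return list with `network` (the filtered `ppin`; its counts gain
#'   `dropped_seeds`) and `report` (a `partner_report`, see
#'   [common_interactors()], with the dropped seeds filled in).
#' @export
filter_network <- function(network, table, tissue, keep_uncovered = FALSE,
                           mode = c("node", "edge_flag")) {
  stopifnot(inherits(network, "ppin"))
  mode <- match.arg(mode)
  seeds_before <- network$nodes$symbol[network$nodes$node_class != "INTERACTOR"]

  if (mode == "edge_flag") {
    e <- network$edges
    keep_e <- vapply(e$tissues, function(t) {
      tolower(tissue) %in% tolower(split_set(t))
    }, logical(1))
    e <- e[keep_e, , drop = FALSE]
    keep_syms <- unique(c(e$symbol_a, e$symbol_b))
    nodes <- network$nodes[network$nodes$symbol %in% keep_syms, , drop = FALSE]
  } else {
    stopifnot(inherits(table, "expression_table"))
    if (nrow(table) == 0) {
      warning("expression table is empty; the filtered network is empty")
      keep <- rep(FALSE, nrow(network$nodes))
    } else {
      keep <- expressed(network$nodes$symbol, tissue, table)
      if (keep_uncovered) {
        keep <- keep | !covered(network$nodes$symbol, tissue, table)
      }
    }
    nodes <- network$nodes[keep, , drop = FALSE]
    e <- network$edges
    keep_e <- e$symbol_a %in% nodes$symbol & e$symbol_b %in% nodes$symbol
    e <- e[keep_e, , drop = FALSE]
  }

  dropped_seeds <- sort(setdiff(seeds_before, nodes$symbol))
  counts <- network$counts
  counts$n_seed_nodes <- sum(nodes$node_class != "INTERACTOR")
  counts$n_interactors <- sum(nodes$node_class == "INTERACTOR")
  counts$dropped_seeds <- dropped_seeds
  out <- new_ppin(nodes, e, counts)
  report <- common_interactors(out)
  report$dropped_seeds <- dropped_seeds
  list(network = out, report = report)
}

#' Class-specific partner sets and their intersection
#'
#' Partners are interactor nodes (never seeds) adjacent to at least one
#' seed of the class in question; the common set is their intersection —
#' the Venn overlap between the RTT and RTT-L first-order neighborhoods.
#'
#' @param network a classified `ppin`.
#' @return list of class `partner_report`: `rtt_partners`, `rttl_partners`,
#'   `common` (sorted character vectors), their sizes `n_rtt_partners`,
#'   `n_rttl_partners`, `n_common`, and `dropped_seeds` (empty here; filled
#'   by [filter_network()]).
#' @export
common_interactors <- function(network) {
  stopifnot(inherits(network, "ppin"))
  cls <- stats::setNames(network$nodes$node_class, network$nodes$symbol)
  e <- network$edges
  partner_of <- function(seed_class) {
    a_seed <- cls[e$symbol_a] == seed_class
    b_seed <- cls[e$symbol_b] == seed_class
    p <- c(e$symbol_b[a_seed], e$symbol_a[b_seed])
    sort(unique(p[cls[p] == "INTERACTOR"]))
  }
  rtt <- partner_of("RTT_SEED")
  rttl <- partner_of("RTTL_SEED")
  common <- intersect(rtt, rttl)
  structure(
    list(
      rtt_partners = rtt, rttl_partners = rttl, common = common,
      n_rtt_partners = length(rtt), n_rttl_partners = length(rttl),
      n_common = length(common), dropped_seeds = character(0)
    ),
    class = "partner_report"
  )
}

#' @export
print.partner_report <- function(x, ...) {
  cat("Partner report\n")
  cat("  RTT partners:   ", x$n_rtt_partners, "\n")
  cat("  RTT-L partners: ", x$n_rttl_partners, "\n")
  cat("  common:         ", x$n_common, "\n")
  if (length(x$dropped_seeds)) {
    cat("  dropped seeds:  ", paste(x$dropped_seeds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a partner report
#'
#' Emits `partner_report.json` with the counts and dropped seeds plus three
#' plain-text symbol lists (`rtt_partners.txt`, `rttl_partners.txt`,
#' `common_interactors.txt`).
#'
#' @param report a `partner_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_partner_report <- function(report, dir) {
  stopifnot(inherits(report, "partner_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_rtt_partners = report$n_rtt_partners,
         n_rttl_partners = report$n_rttl_partners,
         n_common = report$n_common,
         dropped_seeds = report$dropped_seeds),
    file.path(dir, "partner_report.json"), auto_unbox = TRUE, pretty = TRUE
  )
  writeLines(report$rtt_partners, file.path(dir, "rtt_partners.txt"))
  writeLines(report$rttl_partners, file.path(dir, "rttl_partners.txt"))
  writeLines(report$common, file.path(dir, "common_interactors.txt"))
  invisible(dir)
}
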