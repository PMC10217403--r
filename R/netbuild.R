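# First-order PPIN construction: seeds plus all direct interacting
# partners, as a simple undirected graph with node-class annotations.

new_ppin <- function(nodes, edges, counts = NULL) {
  nodes <- nodes[order(nodes$symbol), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges)) {
    edges <- edges[order(edges$symbol_a, edges$symbol_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  counts <- counts %||% list()
  counts$n_nodes <- nrow(nodes)
  counts$n_edges <- nrow(edges)
  structure(list(nodes = nodes, edges = edges, counts = counts), class = "ppin")
}

#' Convert a network to an igraph object
#'
#' Vertices carry the `node_class` attribute; edges carry `evidence`.
#'
#' @param network a `ppin`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppin"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(network$nodes),
                            name = network$nodes$symbol,
                            node_class = network$nodes$node_class)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(
      g,
      rbind(network$edges$symbol_a, network$edges$symbol_b),
      evidence = network$edges$evidence
    )
  }
  g
}

#' Build the first-order interaction network around the seed genes
#'
#' Keeps exactly the interactions with at least one seed endpoint that pass
#' the evidence filter, then annotates every node as `RTT_SEED`,
#' `RTTL_SEED` or `INTERACTOR` (a symbol listed in both seed classes is
#' labelled `RTT_SEED`; the stricter diagnostic class wins). Self-loops are
#' excluded from the edge set but counted, and seeds that end up with no
#' retained interaction are reported as isolated rather than silently
#' dropped — losing a seed is itself a finding (the brain filter does this
#' to CDKL5).
#'
#' @param catalog a `gene_catalog` of seed genes.
#' @param edges an `interaction_edges` data.frame ([read_interactions()]).
#' @param evidence_filter evidence classes to keep; the default keeps only
#'   experimentally validated interactions. `NULL` keeps all.
#' @return a `ppin`: list with `nodes` (symbol, node_class), `edges`, and
#'   `counts` (`n_seed_nodes`, `n_rtt_seed_nodes`, `n_rttl_seed_nodes`,
#'   `n_interactors`, `n_edges`, `n_selfloops_dropped`, `n_isolated_seeds`,
#'   `isolated_seeds`).
#' @examples
#' cat <- parse_catalog(text = "RTT_CLASSICAL\tS1\nRTTL_LITERATURE\tS2")
#' edges <- canonical_edges(data.frame(
#'   symbol_a = c("A", "A"), symbol_b = c("S1", "S2"),
#'   evidence = "experimental", sources = "", tissues = ""))
#' net <- build_first_order(cat, edges)
#' net$counts$n_interactors
#' @export
build_first_order <- function(catalog, edges, evidence_filter = "experimental") {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (nrow(catalog$records) == 0) fail("seed catalog is empty")
  seeds <- seed_symbols(catalog)

  e <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.null(evidence_filter)) e <- e[e$evidence %in% evidence_filter, , drop = FALSE]
  seed_touch <- e$symbol_a %in% seeds | e$symbol_b %in% seeds
  e <- e[seed_touch, , drop = FALSE]
  loops <- e$symbol_a == e$symbol_b
  n_loops <- sum(loops)
  e <- e[!loops, , drop = FALSE]
  e <- e[!duplicated(e[c("symbol_a", "symbol_b")]), , drop = FALSE]

  node_syms <- sort(unique(c(e$symbol_a, e$symbol_b)))
  cls <- classify_symbols(node_syms, catalog)
  nodes <- data.frame(symbol = node_syms, node_class = cls,
                      stringsAsFactors = FALSE)
  isolated <- sort(setdiff(seeds, node_syms))
  counts <- list(
    n_seed_nodes = sum(cls != "INTERACTOR"),
    n_rtt_seed_nodes = sum(cls == "RTT_SEED"),
    n_rttl_seed_nodes = sum(cls == "RTTL_SEED"),
    n_interactors = sum(cls == "INTERACTOR"),
    n_selfloops_dropped = as.integer(n_loops),
    n_isolated_seeds = length(isolated),
    isolated_seeds = isolated
  )
  keep_cols <- intersect(c("symbol_a", "symbol_b", "evidence", "sources", "tissues"),
                         names(e))
  new_ppin(nodes, e[keep_cols], counts)
}

classify_symbols <- function(symbols, catalog) {
  rtt <- rtt_symbols(catalog)
  rttl <- rttl_symbols(catalog)
  ifelse(symbols %in% rtt, "RTT_SEED",
         ifelse(symbols %in% rttl, "RTTL_SEED", "INTERACTOR"))
}

#' Classify the nodes of a network against a seed catalog
#'
#' @param network a `ppin`.
#' @param catalog the `gene_catalog` the network was built from.
#' @param symbols optional subset of node symbols; all of them must be
#'   present in the network.
#' @return named character vector symbol -> class, a partition of the
#'   queried nodes into `RTT_SEED`, `RTTL_SEED`, `INTERACTOR`.
#' @export
classify_nodes <- function(network, catalog, symbols = NULL) {
  stopifnot(inherits(network, "ppin"))
  symbols <- symbols %||% network$nodes$symbol
  absent <- setdiff(symbols, network$nodes$symbol)
  if (length(absent)) {
    fail("node(s) absent from network: ", paste(absent, collapse = ", "))
  }
  stats::setNames(classify_symbols(symbols, catalog), symbols)
}

#' Connected components of a network
#'
#' @param network a `ppin`.
#' @return list of character vectors (sorted node symbols), ordered by
#'   decreasing component size, ties broken by the lexicographically
#'   smallest member.
#' @export
connected_components <- function(network) {
  stopifnot(inherits(network, "ppin"))
  if (nrow(network$nodes) == 0) return(list())
  g <- as_igraph(network)
  comp <- igraph::components(g)
  parts <- split(igraph::V(g)$name, comp$membership)
  parts <- lapply(parts, sort)
  ord <- order(-vapply(parts, length, integer(1)),
               vapply(parts, `[[`, character(1), 1))
  unname(parts[ord])
}

#' @export
print.ppin <- function(x, ...) {
  cat("First-order PPIN:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tab <- table(factor(x$nodes$node_class, levels = NODE_CLASSES))
  for (cl in names(tab)) cat(sprintf("  %-12s %d\n", cl, tab[[cl]]))
  cn <- x$counts
  if (!is.null(cn$n_selfloops_dropped) && cn$n_selfloops_dropped > 0) {
    cat("  self-loops dropped:", cn$n_selfloops_dropped, "\n")
  }
  if (length(cn$isolated_seeds)) {
    cat("  isolated seeds:", paste(cn$isolated_seeds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ppin <- function(object, ...) {
  c(object$counts[c("n_nodes", "n_edges", "n_seed_nodes", "n_interactors")],
    list(n_components = length(connected_components(object))))
}
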