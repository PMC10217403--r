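# Seed-mediated sub-networks and seed-seed direct connectivity.

#' Extract a seed-mediated sub-network
#'
#' The sub-network around a set of anchor seeds is, by default, the induced
#' subgraph on the anchors and their first-order neighbors: all parent
#' edges with both endpoints inside that node set are kept, so
#' neighbor-neighbor interactions stay visible (set `induced = FALSE` to
#' keep only anchor-incident edges, the star view).
#'
#' @param network a `ppin`.
#' @param anchors character vector of anchor symbols. Anchors missing from
#'   the network are reported with a warning; if all are missing, an error.
#' @param include_neighbors include the anchors' first-order neighbors
#'   (default `TRUE`).
#' @param induced keep all edges within the node set (default `TRUE`), or
#'   only anchor-incident edges.
#' @return a `ppin`, always a subgraph of `network`; its counts record
#'   `anchors` and `missing_anchors`.
#' @export
extract_subnetwork <- function(network, anchors, include_neighbors = TRUE,
                               induced = TRUE) {
  stopifnot(inherits(network, "ppin"))
  anchors <- unique(normalize_symbol(anchors))
  present <- intersect(anchors, network$nodes$symbol)
  missing <- setdiff(anchors, present)
  if (!length(present)) {
    fail("none of the anchors are present in the network: ",
         paste(anchors, collapse = ", "))
  }
  if (length(missing)) {
    warning("anchor(s) not in network: ", paste(missing, collapse = ", "))
  }
  e <- network$edges
  incident <- e$symbol_a %in% present | e$symbol_b %in% present
  node_set <- if (include_neighbors) {
    unique(c(present, e$symbol_a[incident], e$symbol_b[incident]))
  } else {
    present
  }
  keep_e <- if (induced) {
    e$symbol_a %in% node_set & e$symbol_b %in% node_set
  } else {
    incident & e$symbol_a %in% node_set & e$symbol_b %in% node_set
  }
  nodes <- network$nodes[network$nodes$symbol %in% node_set, , drop = FALSE]
  counts <- list(
    anchors = sort(present), missing_anchors = sort(missing),
    n_seed_nodes = sum(nodes$node_class != "INTERACTOR"),
    n_interactors = sum(nodes$node_class == "INTERACTOR")
  )
  new_ppin(nodes, e[keep_e, , drop = FALSE], counts)
}

#' Direct seed-seed interactions in a network
#'
#' Lists every edge whose two endpoints are both seed genes, labelled by
#' the class pair — the RTT-L genes in direct contact with RTT genes
#' (HECW2-MECP2 style cross-talk) fall out of this report.
#'
#' @param network a classified `ppin`.
#' @return data.frame: `symbol_a`, `symbol_b`, `class_a`, `class_b`,
#'   `class_pair` (e.g. `"RTT-RTT_L"`), sorted by symbols.
#' @export
seed_adjacency_report <- function(network) {
  stopifnot(inherits(network, "ppin"))
  cls <- stats::setNames(network$nodes$node_class, network$nodes$symbol)
  e <- network$edges
  both_seed <- cls[e$symbol_a] != "INTERACTOR" & cls[e$symbol_b] != "INTERACTOR"
  e <- e[both_seed, , drop = FALSE]
  lab <- function(x) ifelse(x == "RTT_SEED", "RTT", "RTT_L")
  out <- data.frame(
    symbol_a = e$symbol_a, symbol_b = e$symbol_b,
    class_a = unname(cls[e$symbol_a]), class_b = unname(cls[e$symbol_b]),
    stringsAsFactors = FALSE
  )
  out$class_pair <- paste(pmin(lab(out$class_a), lab(out$class_b)),
                          pmax(lab(out$class_a), lab(out$class_b)), sep = "-")
  out <- out[order(out$symbol_a, out$symbol_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dense-cluster view around the top hubs
#'
#' Ranks hubs by a centrality metric and extracts the induced sub-network
#' around the top `k` — a topology-driven stand-in for interactive
#' hub-cluster exploration.
#'
#' @param network a `ppin`.
#' @param table its `centrality_table` (computed if `NULL`).
#' @param metric,k,class_filter passed to [rank_hubs()].
#' @return a `ppin` around the top-k hubs.
#' @export
hub_cluster <- function(network, table = NULL, metric = "degree", k = 10,
                        class_filter = NULL) {
  table <- table %||% centrality_table(network)
  hubs <- rank_hubs(table, metric = metric, k = k, class_filter = class_filter)
  extract_subnetwork(network, hubs, include_neighbors = TRUE, induced = TRUE)
}
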