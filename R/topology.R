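# Network topology: degree, betweenness (raw pair counts, Brandes),
# component-scaled closeness, per-class summaries and hub ranking.

#' Centrality table for a network
#'
#' Computes, per node: degree; betweenness centrality as raw unordered-pair
#' path counts with endpoints excluded (Brandes accumulation, the
#' NetworkAnalyzer convention) plus the normalized variant
#' `raw * 2 / ((N-1)(N-2))`; and closeness centrality in the
#' component-scaled (Wasserman–Faust) form
#' `((n_c - 1) / sum(d)) * ((n_c - 1) / (N - 1))` for a node in a component
#' of size `n_c` inside a graph of `N` nodes — the network is in general
#' disconnected (NTNG1-like satellite components), so plain closeness is
#' undefined; set `closeness_mode = "component"` for the unscaled
#' within-component form. Isolated nodes get closeness 0.
#'
#' @param network a `ppin`.
#' @param closeness_mode `"wasserman_faust"` (default) or `"component"`.
#' @return data.frame of class `centrality_table`: `symbol`, `node_class`,
#'   `degree`, `betweenness_raw`, `betweenness_norm`, `closeness`.
#' @export
centrality_table <- function(network, closeness_mode = c("wasserman_faust", "component")) {
  stopifnot(inherits(network, "ppin"))
  closeness_mode <- match.arg(closeness_mode)
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0) {
    out <- data.frame(symbol = character(0), node_class = character(0),
                      degree = integer(0), betweenness_raw = numeric(0),
                      betweenness_norm = numeric(0), closeness = numeric(0))
    class(out) <- c("centrality_table", "data.frame")
    return(out)
  }
  deg <- igraph::degree(g, loops = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  btw_norm <- if (n > 2) btw * 2 / ((n - 1) * (n - 2)) else rep(0, n)

  d <- igraph::distances(g, weights = NA)
  comp <- igraph::components(g)$membership
  csize <- table(comp)
  clo <- vapply(seq_len(n), function(i) {
    nc <- csize[[as.character(comp[[i]])]]
    if (nc <= 1) return(0)
    s <- sum(d[i, comp == comp[[i]]])
    base <- (nc - 1) / s
    if (closeness_mode == "wasserman_faust" && n > 1) base * (nc - 1) / (n - 1) else base
  }, numeric(1))

  # vertex order equals the sorted node order used by as_igraph()
  out <- data.frame(
    symbol = network$nodes$symbol,
    node_class = network$nodes$node_class,
    degree = as.integer(unname(deg)),
    betweenness_raw = unname(btw),
    betweenness_norm = unname(btw_norm),
    closeness = clo,
    stringsAsFactors = FALSE
  )
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Per-class five-number summary of a centrality metric
#'
#' @param table a `centrality_table`.
#' @param metric one of `"degree"`, `"betweenness_raw"`,
#'   `"betweenness_norm"`, `"closeness"`.
#' @return data.frame: `node_class`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max` (linear-interpolation / type-7 quartiles), one row per class
#'   present.
#' @export
group_summary <- function(table, metric) {
  stopifnot(inherits(table, "centrality_table"))
  if (!metric %in% c("degree", "betweenness_raw", "betweenness_norm", "closeness")) {
    fail("unknown metric '", metric, "'")
  }
  classes <- NODE_CLASSES[NODE_CLASSES %in% table$node_class]
  rows <- lapply(classes, function(cl) {
    v <- table[[metric]][table$node_class == cl]
    q <- stats::quantile(v, probs = c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    data.frame(node_class = cl, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank hub genes by a centrality metric
#'
#' @param table a `centrality_table`.
#' @param metric metric column to rank on (descending); ties broken by
#'   ascending symbol, so the ranking is deterministic.
#' @param k number of hubs to return (`k >= 1`). If `k` exceeds the number
#'   of candidate rows, all are returned with a message.
#' @param class_filter optional node classes to restrict the candidates to.
#' @return character vector of symbols, best first; top-k is always a
#'   prefix of top-(k+1).
#' @export
rank_hubs <- function(table, metric = "degree", k = 10, class_filter = NULL) {
  stopifnot(inherits(table, "centrality_table"), k >= 1)
  if (!metric %in% names(table)) fail("unknown metric '", metric, "'")
  t2 <- table
  if (!is.null(class_filter)) t2 <- t2[t2$node_class %in% class_filter, , drop = FALSE]
  if (k > nrow(t2)) {
    message("rank_hubs: k = ", k, " exceeds ", nrow(t2), " candidate rows; returning all")
    k <- nrow(t2)
  }
  ord <- order(-t2[[metric]], t2$symbol)
  t2$symbol[ord][seq_len(k)]
}

#' Export a centrality table as TSV
#' @param table a `centrality_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(table, path) {
  ord <- order(table$symbol)
  df <- data.frame(
    symbol = table$symbol[ord], class = table$node_class[ord],
    degree = table$degree[ord],
    betweenness_raw = formatC(table$betweenness_raw[ord], format = "g", digits = 12),
    betweenness_norm = formatC(table$betweenness_norm[ord], format = "g", digits = 12),
    closeness = formatC(table$closeness[ord], format = "g", digits = 12)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
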