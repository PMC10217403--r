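# Independent oracles and fixture builders used across the suite.
# The centrality oracle enumerates shortest paths from plain BFS distance
# and path-count matrices; it shares no code path with the package.

# adjacency list (integer indices) from a 2-column edge index matrix
adj_from_edges <- function(n, eidx) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(eidx))) {
    a <- eidx[i, 1]; b <- eidx[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bfs_counts <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Raw betweenness (unordered pairs, endpoints excluded) and
# Wasserman-Faust closeness by direct enumeration over the distance and
# path-count matrices.
oracle_centralities <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- bfs_counts(adj, s)
    D[s, ] <- b$dist
    S[s, ] <- b$sigma
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D) & S > 0
    contrib <- matrix(0, n, n)
    contrib[on_path] <- (outer(S[, v], S[v, ]))[on_path] / S[on_path]
    contrib[v, ] <- 0
    contrib[, v] <- 0
    diag(contrib) <- 0
    bc[v] <- sum(contrib[upper.tri(contrib)])
  }
  clo <- vapply(seq_len(n), function(v) {
    reach <- is.finite(D[v, ])
    nc <- sum(reach)
    if (nc <= 1) return(0)
    (nc - 1) / sum(D[v, reach]) * (nc - 1) / max(1, n - 1)
  }, numeric(1))
  list(betweenness = bc, closeness = clo)
}

# hypergeometric pmf over k = 0..n by exhaustive enumeration of all
# size-n draws from {1..N}, annotated genes being {1..K}
enum_hyper_pmf <- function(N, K, n) {
  if (n == 0) return(c(1, numeric(0)))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  tabulate(overlaps + 1L, nbins = n + 1L) / ncol(draws)
}

# --- fixture builders -------------------------------------------------

edge_df <- function(a, b, evidence = "experimental") {
  data.frame(symbol_a = pmin(a, b), symbol_b = pmax(a, b),
             evidence = evidence, sources = "", tissues = "",
             stringsAsFactors = FALSE)
}

canon <- function(df) rettnet:::canonical_edges(df)

# network over the given edges with every endpoint treated as a seed, so
# all edges are retained; convenient for pure graph-algorithm tests
graph_ppin <- function(a, b) {
  syms <- sort(unique(c(a, b)))
  cat <- parse_catalog(text = paste0("RTTL_LITERATURE\t",
                                     paste(syms, collapse = ", ")))
  build_first_order(cat, canon(edge_df(a, b)))
}

# Erdos-Renyi edge index matrix on n vertices
random_edges <- function(n, p) {
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

# a classified seed network: RTT seeds R1.., RTT-L seeds L1.., interactors X..
seeded_catalog <- function(n_rtt, n_rttl) {
  parse_catalog(text = paste0(
    "RTT_CLASSICAL\t", paste(sprintf("R%d", seq_len(n_rtt)), collapse = ", "),
    "\nRTTL_LITERATURE\t", paste(sprintf("L%d", seq_len(n_rttl)), collapse = ", ")
  ))
}
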