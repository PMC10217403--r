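expr_tab <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(symbol = r[[1]], tissue = r[[2]], level = r[[3]],
               stringsAsFactors = FALSE)
  }))
  read_expression(text = paste(
    c("symbol\ttissue\tlevel",
      paste(df$symbol, df$tissue, df$level, sep = "\t")), collapse = "\n"))
}

test_that("the expression rule: any level but not_detected counts, absence drops", {
  tab <- expr_tab(c("A", "brain", "low"), c("B", "brain", "not_detected"))
  expect_true(expressed("A", "brain", tab))
  expect_false(expressed("B", "brain", tab))
  expect_false(expressed("CDKL5", "brain", tab)) # no record at all
  expect_false(expressed("A", "liver", tab))
})

test_that("filtering keeps expressed nodes and edges between them", {
  net <- graph_ppin(c("A", "B"), c("B", "C"))
  tab <- expr_tab(c("A", "brain", "low"), c("B", "brain", "medium"),
                  c("C", "brain", "not_detected"))
  res <- filter_network(net, tab, "brain")
  expect_setequal(res$network$nodes$symbol, c("A", "B"))
  expect_equal(nrow(res$network$edges), 1)

  # all expressed: identity
  tab2 <- expr_tab(c("A", "brain", "low"), c("B", "brain", "high"),
                   c("C", "brain", "low"))
  res2 <- filter_network(net, tab2, "brain")
  expect_equal(res2$network$nodes, net$nodes)
  expect_equal(res2$network$edges, net$edges)

  # empty table: warning, empty network
  empty <- read_expression(text = "symbol\ttissue\tlevel")
  expect_warning(res3 <- filter_network(net, empty, "brain"), "empty")
  expect_equal(nrow(res3$network$nodes), 0)
})

test_that("a seed with no expression record is dropped and reported", {
  cat <- seeded_catalog(2, 2)
  net <- build_first_order(cat, canon(edge_df(
    c("R1", "R2", "L1", "L2"), c("X1", "X2", "X1", "X3"))))
  tab <- expr_tab(c("R1", "brain", "low"), c("L1", "brain", "low"),
                  c("L2", "brain", "low"), c("X1", "brain", "low"),
                  c("X2", "brain", "low"), c("X3", "brain", "medium"))
  res <- filter_network(net, tab, "brain") # R2 uncovered
  expect_equal(res$report$dropped_seeds, "R2")
  expect_false("R2" %in% res$network$nodes$symbol)
  # keep_uncovered mode retains it instead
  res2 <- filter_network(net, tab, "brain", keep_uncovered = TRUE)
  expect_true("R2" %in% res2$network$nodes$symbol)
})

test_that("filtering is idempotent and monotone in expression records", {
  set.seed(31)
  for (rep in 1:10) {
    cfg <- synthetic_config(n_nodes = 120, n_rtt_seeds = 3, n_rttl_seeds = 8,
                            planted_common_k = 5, p_uncovered = 0.2,
                            p_not_detected = 0.3, rng_seed = rep)
    sim <- generate_interactome(cfg)
    net <- build_first_order(sim$catalog, sim$edges)
    tab <- generate_expression(cfg, net$nodes$symbol)
    once <- filter_network(net, tab, "brain")
    twice <- filter_network(once$network, tab, "brain")
    expect_equal(twice$network$nodes, once$network$nodes)
    expect_equal(twice$network$edges, once$network$edges)
    # subgraph containment
    expect_true(all(once$network$nodes$symbol %in% net$nodes$symbol))

    # add records for every missing / not-detected symbol: network can only grow
    missing <- setdiff(net$nodes$symbol, tab$symbol[tab$level != "not_detected"])
    grow <- sample(missing, ceiling(length(missing) / 2))
    if (length(grow)) {
      tab2 <- rbind(as.data.frame(tab)[!(tab$symbol %in% grow), ],
                    data.frame(symbol = grow, tissue = "brain", level = "low"))
      class(tab2) <- class(tab)
      more <- filter_network(net, tab2, "brain")
      expect_true(all(once$network$nodes$symbol %in% more$network$nodes$symbol))
      expect_true(all(paste(once$network$edges$symbol_a, once$network$edges$symbol_b)
                      %in% paste(more$network$edges$symbol_a, more$network$edges$symbol_b)))
    }
  }
})

test_that("edge-flag filter mode keeps edges flagged for the tissue", {
  cat <- seeded_catalog(1, 1)
  edges <- canon(data.frame(
    symbol_a = c("R1", "L1"), symbol_b = c("X1", "X2"),
    evidence = "experimental", sources = "",
    tissues = c("brain;liver", "liver"), stringsAsFactors = FALSE))
  net <- build_first_order(cat, edges)
  res <- filter_network(net, table = NULL, tissue = "brain", mode = "edge_flag")
  expect_equal(nrow(res$network$edges), 1)
  expect_setequal(res$network$nodes$symbol, c("R1", "X1"))
})

test_that("partner sets and their intersection follow adjacency by class", {
  cat <- seeded_catalog(1, 1)
  net <- build_first_order(cat, canon(edge_df(
    c("R1", "L1", "R1", "L1"), c("X", "X", "Y", "Z"))))
  rep <- common_interactors(net)
  expect_equal(rep$common, "X")
  expect_setequal(rep$rtt_partners, c("X", "Y"))
  expect_setequal(rep$rttl_partners, c("X", "Z"))
  # partners never contain seeds
  net2 <- build_first_order(cat, canon(edge_df(c("R1", "R1"), c("L1", "X"))))
  rep2 <- common_interactors(net2)
  expect_false("L1" %in% rep2$rtt_partners)
  expect_equal(rep2$n_common, 0)
})

test_that("common set is bounded by both partner sets on random instances", {
  set.seed(77)
  for (rep in 1:15) {
    cfg <- synthetic_config(n_nodes = 80, n_rtt_seeds = 2, n_rttl_seeds = 6,
                            planted_common_k = sample(0:4, 1), rng_seed = rep)
    sim <- generate_interactome(cfg)
    net <- build_first_order(sim$catalog, sim$edges)
    pr <- common_interactors(net)
    expect_lte(pr$n_common, min(pr$n_rtt_partners, pr$n_rttl_partners))
    expect_true(all(pr$common %in% pr$rtt_partners))
    expect_true(all(pr$common %in% pr$rttl_partners))
  }
})
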