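test_that("first-order build keeps exactly seed-incident edges", {
  cat <- parse_catalog(text = "RTT_CLASSICAL\tS")
  edges <- canon(edge_df(c("S", "A"), c("A", "B")))
  net <- build_first_order(cat, edges)
  expect_setequal(net$nodes$symbol, c("S", "A"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$counts$n_interactors, 1)

  # a seed with only a self-loop is isolated, the loop counted
  loop <- build_first_order(cat, canon(edge_df("S", "S")))
  expect_equal(nrow(loop$edges), 0)
  expect_equal(loop$counts$n_selfloops_dropped, 1)
  expect_equal(loop$counts$isolated_seeds, "S")

  cat2 <- parse_catalog(text = "RTT_CLASSICAL\tS1, S2")
  net2 <- build_first_order(cat2, canon(edge_df(c("S1", "S2", "S1"),
                                                c("A", "A", "S2"))))
  expect_equal(nrow(net2$edges), 3)
  expect_equal(net2$counts$n_interactors, 1)

  empty_cat <- parse_catalog(text = "RTT_CLASSICAL\tX")
  empty_cat$records <- empty_cat$records[0, ]
  expect_error(build_first_order(empty_cat, edges), "empty")
})

test_that("evidence filter restricts retained edges", {
  cat <- parse_catalog(text = "RTT_CLASSICAL\tS")
  edges <- canon(edge_df(c("S", "S"), c("A", "B"),
                         evidence = c("experimental", "predicted")))
  net <- build_first_order(cat, edges)
  expect_equal(net$edges$symbol_b, "S") # only S-A survives (A < S)
  all_net <- build_first_order(cat, edges, evidence_filter = NULL)
  expect_equal(nrow(all_net$edges), 2)
})

test_that("node classes partition the network with RTT precedence", {
  cat <- parse_catalog(text = paste0(
    "RTT_CLASSICAL\tMECP2\nRTT_ATYPICAL\tCDKL5\n",
    "RTTL_LITERATURE\tMECP2, HECW2"))
  net <- build_first_order(cat, canon(edge_df(
    c("MECP2", "MECP2", "CDKL5", "HECW2"),
    c("X1", "HECW2", "X1", "X2"))))
  cls <- classify_nodes(net, cat)
  expect_equal(unname(cls[["MECP2"]]), "RTT_SEED") # dual-listed, RTT wins
  expect_equal(unname(cls[["HECW2"]]), "RTTL_SEED")
  expect_equal(unname(cls[["X1"]]), "INTERACTOR")
  expect_equal(sum(table(cls)), nrow(net$nodes))
  expect_error(classify_nodes(net, cat, "ABSENT"), "absent")
})

test_that("retained edges match a brute-force membership scan", {
  for (rep in 1:20) {
    set.seed(rep)
    n <- sample(10:40, 1)
    syms <- sprintf("G%02d", seq_len(n))
    eidx <- random_edges(n, 0.15)
    if (!nrow(eidx)) next
    a <- syms[eidx[, 1]]; b <- syms[eidx[, 2]]
    seeds <- sample(syms, sample(2:5, 1))
    cat <- parse_catalog(text = paste0("RTT_CLASSICAL\t",
                                       paste(seeds, collapse = ", ")))
    net <- build_first_order(cat, canon(edge_df(a, b)))
    # oracle: scan every input edge for seed endpoint membership
    keep <- (a %in% seeds | b %in% seeds) & a != b
    oracle <- unique(paste(pmin(a, b)[keep], pmax(a, b)[keep]))
    expect_setequal(paste(net$edges$symbol_a, net$edges$symbol_b), oracle)
    # first-order property, checked exhaustively
    expect_true(all(net$edges$symbol_a %in% seeds | net$edges$symbol_b %in% seeds))
  }
})

test_that("build is monotone in the seed set", {
  set.seed(11)
  n <- 30
  syms <- sprintf("G%02d", seq_len(n))
  eidx <- random_edges(n, 0.2)
  a <- syms[eidx[, 1]]; b <- syms[eidx[, 2]]
  edges <- canon(edge_df(a, b))
  seeds <- sample(syms, 3)
  small <- build_first_order(
    parse_catalog(text = paste0("RTT_CLASSICAL\t", paste(seeds, collapse = ", "))),
    edges)
  big <- build_first_order(
    parse_catalog(text = paste0("RTT_CLASSICAL\t",
                                paste(c(seeds, sample(setdiff(syms, seeds), 2)),
                                      collapse = ", "))),
    edges)
  expect_true(all(small$nodes$symbol %in% big$nodes$symbol))
  expect_true(all(paste(small$edges$symbol_a, small$edges$symbol_b) %in%
                  paste(big$edges$symbol_a, big$edges$symbol_b)))
})

test_that("connected components partition the graph, satellites separate", {
  cat <- parse_catalog(text = "RTT_CLASSICAL\tS1, S2")
  net <- build_first_order(cat, canon(edge_df(c("S1", "S2"), c("A", "B"))))
  comps <- connected_components(net)
  expect_length(comps, 2)
  expect_setequal(unlist(comps), net$nodes$symbol)

  # NTNG1-like satellite: seed attached to its four partners only
  cat2 <- parse_catalog(text = "RTT_CLASSICAL\tNTNG1\nRTTL_LITERATURE\tHTT")
  net2 <- build_first_order(cat2, canon(edge_df(
    c("NTNG1", "NTNG1", "NTNG1", "NTNG1", "HTT", "HTT", "HTT"),
    c("HSPA6", "LRRC4", "LRRC4C", "GAS6", "P1", "P2", "P3"))))
  comps2 <- connected_components(net2)
  sat <- comps2[[vapply(comps2, function(cp) "NTNG1" %in% cp, logical(1)) |> which()]]
  expect_length(sat, 5)
  expect_setequal(sat, c("NTNG1", "HSPA6", "LRRC4", "LRRC4C", "GAS6"))

  one <- connected_components(graph_ppin(c("A", "B", "C"), c("B", "C", "A")))
  expect_length(one, 1)
})
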