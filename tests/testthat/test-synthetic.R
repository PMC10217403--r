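small_cfg <- function(seed = 42, ...) {
  synthetic_config(n_nodes = 150, n_rtt_seeds = 3, n_rttl_seeds = 8,
                   planted_common_k = 5, n_terms = 10,
                   term_size_range = c(5, 15), planted_term_K = 8,
                   planted_term_k = 6, rng_seed = seed, ...)
}

test_that("generators are byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulate_inputs(small_cfg(), d1)
  p2 <- simulate_inputs(small_cfg(), d2)
  for (key in c("catalog", "interactions", "expression", "gmt")) {
    expect_identical(readLines(p1[[key]]), readLines(p2[[key]]),
                     label = paste("file", key))
  }
  # a different seed changes the interactome
  d3 <- withr::local_tempdir()
  p3 <- simulate_inputs(small_cfg(seed = 43), d3)
  expect_false(identical(readLines(p1$interactions), readLines(p3$interactions)))
})

test_that("the attachment backbone is connected with heavy-tailed degrees", {
  cfg <- synthetic_config(n_nodes = 260, n_rtt_seeds = 2, n_rttl_seeds = 4,
                          planted_common_k = 0, n_seed_seed_edges = 0,
                          rng_seed = 9)
  sim <- generate_interactome(cfg)
  seeds <- seed_symbols(sim$catalog)
  bb <- sim$edges[!(sim$edges$symbol_a %in% seeds) &
                  !(sim$edges$symbol_b %in% seeds), ]
  g <- igraph::graph_from_edgelist(as.matrix(bb[c("symbol_a", "symbol_b")]),
                                   directed = FALSE)
  expect_true(igraph::is_connected(g))
  deg <- igraph::degree(g)
  expect_gte(max(deg), 3 * stats::median(deg))
})

test_that("planted common-interactor counts are recovered exactly", {
  for (k in c(0, 5, 20)) {
    cfg <- synthetic_config(n_nodes = 150, n_rtt_seeds = 3, n_rttl_seeds = 8,
                            planted_common_k = k, rng_seed = 100 + k)
    sim <- generate_interactome(cfg)
    net <- build_first_order(sim$catalog, sim$edges)
    expect_equal(common_interactors(net)$n_common, k)
  }
  expect_error(
    generate_interactome(synthetic_config(n_nodes = 12, n_rtt_seeds = 4,
                                          n_rttl_seeds = 6,
                                          planted_common_k = 5)),
    "infeasible")
})

test_that("expression generator honours coverage probabilities and forcing", {
  cfg0 <- small_cfg()
  syms <- sprintf("G%03d", 1:200)

  full <- synthetic_config(n_nodes = 150, n_rtt_seeds = 3, n_rttl_seeds = 8,
                           planted_common_k = 5, p_uncovered = 0,
                           p_not_detected = 0, rng_seed = 1)
  tab <- generate_expression(full, syms)
  expect_equal(nrow(tab), 200)
  expect_true(all(tab$level != "not_detected"))

  none <- synthetic_config(n_nodes = 150, n_rtt_seeds = 3, n_rttl_seeds = 8,
                           planted_common_k = 5, p_uncovered = 0,
                           p_not_detected = 1, rng_seed = 1)
  tab2 <- generate_expression(none, syms)
  expect_true(all(tab2$level == "not_detected"))

  forced <- generate_expression(cfg0, syms, force_uncovered = "G001")
  expect_false("G001" %in% forced$symbol)
})

test_that("forced-uncovered seeds drop out of the filtered network", {
  cfg <- synthetic_config(n_nodes = 150, n_rtt_seeds = 3, n_rttl_seeds = 8,
                          planted_common_k = 5, p_uncovered = 0,
                          p_not_detected = 0, rng_seed = 4)
  sim <- generate_interactome(cfg)
  net <- build_first_order(sim$catalog, sim$edges)
  victim <- rtt_symbols(sim$catalog)[1]
  tab <- generate_expression(cfg, net$nodes$symbol, force_uncovered = victim)
  res <- filter_network(net, tab, "brain")
  expect_equal(res$report$dropped_seeds, victim)
  # with nothing forced and full coverage the filter is the identity
  tab_all <- generate_expression(cfg, net$nodes$symbol)
  res_all <- filter_network(net, tab_all, "brain")
  expect_equal(res_all$network$nodes, net$nodes)
  expect_equal(res_all$network$edges, net$edges)
})

test_that("the planted gene-set term has the stated size and overlap", {
  cfg <- small_cfg()
  universe <- sprintf("U%03d", 1:300)
  query <- sprintf("U%03d", 1:20)
  terms <- generate_gmt(cfg, universe, query)
  planted <- terms[terms$term_id == "PLANTED", ]
  expect_equal(length(planted$members[[1]]), cfg$planted_term_K)
  expect_equal(length(intersect(planted$members[[1]], query)),
               cfg$planted_term_k)
  sizes <- lengths(terms$members[terms$term_id != "PLANTED"])
  expect_true(all(sizes >= 5 & sizes <= 15))
  expect_error(generate_gmt(cfg, universe[1:6], query), "exceeds the universe")
})

test_that("a zero-overlap planted term is absent from enrichment output", {
  cfg <- synthetic_config(n_nodes = 150, n_rtt_seeds = 3, n_rttl_seeds = 8,
                          planted_common_k = 5, n_terms = 5,
                          term_size_range = c(5, 10), planted_term_K = 6,
                          planted_term_k = 0, rng_seed = 2)
  universe <- sprintf("U%03d", 1:300)
  query <- sprintf("U%03d", 1:20)
  terms <- generate_gmt(cfg, universe, query)
  res <- run_enrichment(query, terms, background = universe)
  expect_false("PLANTED" %in% res$term_id)
  expect_equal(attr(res, "m")[["GO_BP"]], 6) # still counted in m
})
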