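test_that("upper-tail p matches exhaustive draws on small cases", {
  # universe of 10, 5 annotated, query of 4, all 4 annotated: 5/210
  expect_equal(hypergeom_upper(10, 5, 4, 4), 5 / choose(10, 4), tolerance = 1e-14)
  expect_equal(hypergeom_upper(10, 5, 4, 0), 1)
  expect_equal(hypergeom_upper(8, 8, 3, 3), 1) # term is the whole universe
  expect_error(hypergeom_upper(10, 5, 4, 5), "invalid")
  expect_error(hypergeom_upper(10, 12, 4, 2), "invalid")
})

test_that("two-sided p uses the minimum-likelihood rule", {
  # symmetric case: P(X=4) + P(X=0)
  d <- dhyper(0:4, 4, 4, 4)
  expect_equal(hypergeom_two_sided(8, 4, 4, 4), d[[5]] + d[[1]], tolerance = 1e-12)
  # at the mode the whole support is included
  expect_equal(hypergeom_two_sided(8, 4, 4, 2), 1, tolerance = 1e-12)
  # never below either tail alone, and reduces to upper at the maximum
  expect_gte(hypergeom_two_sided(10, 5, 4, 4) + 1e-15, hypergeom_upper(10, 5, 4, 4))
})

test_that("upper tail is monotone non-increasing in the overlap", {
  for (case in list(c(30, 10, 8), c(12, 6, 6), c(50, 25, 10))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    ks <- max(0, n - (N - K)):min(K, n)
    ps <- vapply(ks, function(k) hypergeom_upper(N, K, n, k), numeric(1))
    expect_true(all(diff(ps) <= 1e-15))
  }
})

gmt_text <- function(...) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("enrichment reports overlap terms with Bonferroni correction", {
  terms <- read_gmt(gmt_text(paste(c("T1", "d", LETTERS[1:5]), collapse = "\t"),
                             paste(c("T2", "d", LETTERS[1:10]), collapse = "\t")))
  res <- run_enrichment(LETTERS[1:4], terms, background = LETTERS[1:10])
  expect_s3_class(res, "enrichment_result")
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$k, 4)
  expect_equal(t1$p_raw, 5 / choose(10, 4), tolerance = 1e-12)
  # two testable terms: m = 2
  expect_equal(t1$p_adj, min(1, 2 * t1$p_raw), tolerance = 1e-12)
  expect_equal(attr(res, "m")[["GO_BP"]], 2)
  # sorted by adjusted p then term id
  expect_equal(res$term_id, res$term_id[order(res$p_adj, res$term_id)])
})

test_that("zero-overlap terms count toward m but are not reported", {
  terms <- read_gmt(gmt_text("HIT\td\tA\tB", "MISS\td\tX\tY", "GONE\td\tQ9"))
  res <- run_enrichment(c("A", "B"), terms,
                        background = c("A", "B", "C", "X", "Y", "Z"))
  expect_equal(res$term_id, "HIT")
  expect_equal(attr(res, "m")[["GO_BP"]], 2) # GONE has no background members
  expect_equal(res$p_adj, pmin(1, 2 * res$p_raw))
})

test_that("correction scope switches between per-source and global m", {
  go <- read_gmt(gmt_text("G1\td\tA\tB", "G2\td\tA\tC"), source = "GO_BP")
  kegg <- read_gmt(gmt_text("K1\td\tA\tB"), source = "KEGG")
  bg <- c("A", "B", "C", "D", "E", "F")
  per <- run_enrichment(c("A", "B"), list(go, kegg), background = bg)
  glob <- run_enrichment(c("A", "B"), list(go, kegg), background = bg,
                         correction_scope = "global")
  k_per <- per[per$term_id == "K1", ]
  k_glob <- glob[glob$term_id == "K1", ]
  expect_equal(k_per$p_adj, min(1, 1 * k_per$p_raw))
  expect_equal(k_glob$p_adj, min(1, 3 * k_glob$p_raw))
})

test_that("enrichment output is invariant to query and source ordering", {
  go <- read_gmt(gmt_text("G1\td\tA\tB\tC", "G2\td\tC\tD\tE"), source = "GO_BP")
  bg <- LETTERS[1:8]
  r1 <- run_enrichment(c("A", "C", "B"), go, background = bg)
  r2 <- run_enrichment(c("C", "B", "A"), go, background = rev(bg))
  expect_equal(as.data.frame(r1), as.data.frame(r2), ignore_attr = TRUE)
})

test_that("empty query after background restriction errors", {
  go <- read_gmt(gmt_text("G1\td\tA\tB"))
  expect_error(run_enrichment("Z", go, background = c("A", "B")),
               "query is empty")
})

test_that("pathway mapping splits members by seed class and common interactors", {
  cat <- seeded_catalog(2, 3)
  net <- build_first_order(cat, canon(edge_df(
    c("R1", "L1", "R2", "L2"), c("X", "X", "Y", "Y"))))
  pm <- map_pathway(net, cat, c("R1", "L1", "L2", "X", "OTHER"))
  expect_equal(pm$rtt_members, "R1")
  expect_setequal(pm$rttl_members, c("L1", "L2"))
  expect_equal(pm$shared_interactors, "X") # Y is common too but not a pathway member
  expect_equal(pm$n_shared, 1)
  # disjoint pathway: empty map, no error
  pm2 <- map_pathway(net, cat, c("Q1", "Q2"))
  expect_equal(pm2$n_rtt + pm2$n_rttl + pm2$n_shared, 0)
  expect_error(map_pathway(net, cat, character(0)), "no members")
})
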