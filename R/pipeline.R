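# End-to-end orchestration: catalog -> first-order network -> topology ->
# tissue filter -> filtered topology -> sub-networks -> common interactors
# -> enrichment -> report, with every intermediate written to disk.

#' Load a pipeline configuration file
#'
#' YAML key-value file; see [run_pipeline()] for the recognised keys.
#' Relative input paths are resolved against the file's directory.
#'
#' @param path path to a YAML configuration.
#' @return named list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    ifelse(is.na(p) | grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("catalog", "interactions", "expression")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- fix(cfg[[key]])
  }
  if (!is.null(cfg$gmt)) cfg$gmt <- lapply(cfg$gmt, fix)
  cfg
}

#' Run the seed-gene interactome pipeline
#'
#' Executes the full analysis and writes all intermediates and a
#' reproducible report to `output_dir`. Re-running with identical inputs
#' produces identical reports: nothing in the report depends on time,
#' hostnames or the output location. A failing stage aborts with the stage
#' name and cause, and leaves a `FAILED` marker next to whatever partial
#' outputs were already written.
#'
#' @param config named list (or the path to a YAML file, see
#'   [load_pipeline_config()]) with keys:
#'   \describe{
#'     \item{catalog}{path to the seed-list file ([parse_catalog()]).}
#'     \item{interactions}{path to an interaction table in the package's
#'       canonical dialect ([write_interactions()]).}
#'     \item{expression}{path to an expression table.}
#'     \item{gmt}{named list `source -> path` of GMT files.}
#'     \item{tissue}{tissue to restrict to (default `"brain"`).}
#'     \item{evidence}{evidence filter (default `"experimental"`).}
#'     \item{alpha, sidedness, universe, correction_scope}{enrichment
#'       options; `universe` is `"sources"` (default) or `"network"`.}
#'     \item{top_k}{hubs reported per node class (default 10).}
#'   }
#' @param output_dir directory for artifacts (created if needed).
#' @return the run report (list of class `rettnet_report`), invisibly;
#'   also written as `report.json` and `report.txt`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- load_pipeline_config(config)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(output_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), failed_marker)
      fail("stage '", name, "': ", conditionMessage(e))
    })
  }
  msg <- function(...) message("[rettnet] ", ...)

  tissue <- config$tissue %||% "brain"
  evidence <- config$evidence %||% "experimental"
  top_k <- config$top_k %||% 10

  msg("stage catalog")
  catalog <- stage("catalog", {
    if (is.null(config$catalog)) fail("no catalog path configured")
    parse_catalog(config$catalog)
  })

  msg("stage build")
  network <- stage("build", {
    if (is.null(config$interactions)) fail("no interactions path configured")
    edges <- read_interactions_canonical(config$interactions)
    net <- build_first_order(catalog, edges, evidence_filter = evidence)
    write_graph_file(net, file.path(output_dir, "network_full.tsv"), "tsv")
    net
  })

  msg("stage topology")
  cent_full <- stage("topology", {
    ct <- centrality_table(network)
    write_centrality(ct, file.path(output_dir, "centrality_full.tsv"))
    ct
  })

  msg("stage tissue_filter (", tissue, ")")
  filt <- stage("tissue_filter", {
    if (is.null(config$expression)) fail("no expression path configured")
    expr_tab <- read_expression(config$expression)
    res <- filter_network(network, expr_tab, tissue)
    write_graph_file(res$network,
                     file.path(output_dir, "network_tissue.tsv"), "tsv")
    write_partner_report(res$report, output_dir)
    res
  })

  msg("stage topology_filtered")
  cent_filt <- stage("topology_filtered", {
    ct <- centrality_table(filt$network)
    write_centrality(ct, file.path(output_dir, "centrality_tissue.tsv"))
    ct
  })

  msg("stage subnet")
  seed_edges <- stage("subnet", {
    rtt_in_net <- intersect(rtt_symbols(catalog), network$nodes$symbol)
    if (length(rtt_in_net)) {
      sub <- extract_subnetwork(network, rtt_in_net)
      write_graph_file(sub, file.path(output_dir, "subnet_rtt.tsv"), "tsv")
    }
    seed_adjacency_report(network)
  })

  msg("stage enrich")
  enr <- stage("enrich", {
    if (is.null(config$gmt) || !length(config$gmt)) {
      NULL
    } else {
      sources <- lapply(names(config$gmt), function(src) {
        read_gmt(config$gmt[[src]], source = src)
      })
      background <- switch(config$universe %||% "sources",
        sources = NULL,
        network = network$nodes$symbol,
        fail("unknown universe mode '", config$universe, "'")
      )
      res <- run_enrichment(
        query = seed_symbols(catalog), sources = sources,
        background = background,
        alpha = config$alpha %||% 0.05,
        sidedness = config$sidedness %||% "upper",
        correction_scope = config$correction_scope %||% "per_source"
      )
      write_enrichment(res, file.path(output_dir, "enrichment.tsv"))
      res
    }
  })

  msg("stage report")
  report <- stage("report", {
    hubs_by_class <- lapply(
      stats::setNames(NODE_CLASSES, NODE_CLASSES),
      function(cl) {
        if (!any(cent_full$node_class == cl)) return(character(0))
        rank_hubs(cent_full, "degree",
                  k = min(top_k, sum(cent_full$node_class == cl)),
                  class_filter = cl)
      }
    )
    enr_summary <- if (is.null(enr)) NULL else {
      by_src <- split(enr$significant, enr$source)
      lapply(by_src, function(s) list(n_reported = length(s),
                                      n_significant = sum(s)))
    }
    cfg_echo <- config[setdiff(names(config), "output_dir")]
    rep <- list(
      catalog = list(n_rtt = catalog$n_rtt, n_rttl = catalog$n_rttl),
      network = list(
        n_nodes = network$counts$n_nodes, n_edges = network$counts$n_edges,
        n_seed_nodes = network$counts$n_seed_nodes,
        n_interactors = network$counts$n_interactors,
        n_selfloops_dropped = network$counts$n_selfloops_dropped,
        n_isolated_seeds = network$counts$n_isolated_seeds,
        n_components = length(connected_components(network))
      ),
      tissue_filtered = list(
        tissue = tissue,
        n_nodes = filt$network$counts$n_nodes,
        n_edges = filt$network$counts$n_edges,
        n_rtt_partners = filt$report$n_rtt_partners,
        n_rttl_partners = filt$report$n_rttl_partners,
        n_common = filt$report$n_common,
        dropped_seeds = filt$report$dropped_seeds
      ),
      seed_adjacency = list(
        n_seed_seed_edges = nrow(seed_edges),
        pairs = if (nrow(seed_edges)) paste(seed_edges$symbol_a,
                                            seed_edges$symbol_b,
                                            sep = "-") else character(0)
      ),
      top_hubs = hubs_by_class,
      enrichment = enr_summary,
      version = as.character(utils::packageVersion("rettnet")),
      config = cfg_echo
    )
    class(rep) <- "rettnet_report"
    rep
  })

  jsonlite::write_json(unclass(report), file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(format_report(report), file.path(output_dir, "report.txt"))
  invisible(report)
}

format_report <- function(report) {
  c(
    "rettnet pipeline report",
    sprintf("  seed catalog: %d RTT, %d RTT-L distinct genes",
            report$catalog$n_rtt, report$catalog$n_rttl),
    sprintf("  first-order network: %d nodes, %d edges (%d interactors, %d isolated seeds)",
            report$network$n_nodes, report$network$n_edges,
            report$network$n_interactors, report$network$n_isolated_seeds),
    sprintf("  %s-restricted: %d nodes, %d edges",
            report$tissue_filtered$tissue, report$tissue_filtered$n_nodes,
            report$tissue_filtered$n_edges),
    sprintf("  partners: %d RTT, %d RTT-L, %d common",
            report$tissue_filtered$n_rtt_partners,
            report$tissue_filtered$n_rttl_partners,
            report$tissue_filtered$n_common),
    if (length(report$tissue_filtered$dropped_seeds)) {
      sprintf("  seeds dropped by the filter: %s",
              paste(report$tissue_filtered$dropped_seeds, collapse = ", "))
    },
    sprintf("  seed-seed edges: %d", report$seed_adjacency$n_seed_seed_edges),
    if (!is.null(report$enrichment)) {
      vapply(names(report$enrichment), function(src) {
        sprintf("  enrichment [%s]: %d terms reported, %d significant",
                src, report$enrichment[[src]]$n_reported,
                report$enrichment[[src]]$n_significant)
      }, character(1))
    },
    sprintf("  rettnet version %s", report$version)
  )
}

#' @export
print.rettnet_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Write synthetic pipeline inputs to a directory
#'
#' Convenience wrapper used by examples, tests and the acceptance script:
#' generates a synthetic interactome, expression table and GMT collection
#' under one configuration and writes them, plus a ready-to-run pipeline
#' YAML, into `dir`.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @param catalog optional `gene_catalog` for the seeds (see
#'   [generate_interactome()]).
#' @param force_uncovered symbols forced to lack expression records.
#' @return named list of the written paths, invisibly.
#' @export
simulate_inputs <- function(config, dir, catalog = NULL,
                            force_uncovered = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_interactome(config, catalog)
  seed_note <- paste0("rng_seed: ", config$rng_seed)
  paths <- list(
    catalog = file.path(dir, "catalog.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    expression = file.path(dir, "expression.tsv"),
    gmt = file.path(dir, "terms.gmt"),
    config = file.path(dir, "pipeline.yaml")
  )
  write_catalog(sim$catalog, paths$catalog)
  write_interactions(sim$edges, paths$interactions, header_comment = seed_note)
  symbols <- unique(c(sim$edges$symbol_a, sim$edges$symbol_b))
  expr <- generate_expression(config, symbols, force_uncovered = force_uncovered)
  write_expression(expr, paths$expression, header_comment = seed_note)
  terms <- generate_gmt(config, universe = symbols,
                        query = seed_symbols(sim$catalog))
  write_gmt(terms, paths$gmt, header_comment = seed_note)
  yaml::write_yaml(list(
    catalog = "catalog.tsv", interactions = "interactions.tsv",
    expression = "expression.tsv", gmt = list(GO_BP = "terms.gmt"),
    tissue = config$tissue, evidence = "experimental"
  ), paths$config)
  invisible(paths)
}
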