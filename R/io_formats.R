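# Readers and writers: IID-style interaction tables, HPA-style protein
# expression tables, GMT gene-set collections, and Cytoscape-readable
# graph exports (TSV edge list, SIF, GraphML).

#' Describe the column layout of an interaction table
#'
#' IID releases rename and reorder columns, so the reader takes a small
#' dialect configuration instead of hard-coding positions.
#'
#' @param symbol_a,symbol_b names of the two gene-symbol columns.
#' @param evidence name of the evidence-type column, or `NULL` if absent
#'   (all rows are then treated as `experimental`).
#' @param sources name of a database-tag column (entries split on `;` or
#'   `,`), or `NULL`.
#' @param tissue_columns character vector of per-tissue flag columns (a
#'   value of `1`/`y`/`yes`/`true` flags the edge for that tissue), or
#'   `NULL`.
#' @return a list of class `interaction_dialect`.
#' @export
interaction_dialect <- function(symbol_a = "symbol1", symbol_b = "symbol2",
                                evidence = "evidence_type", sources = NULL,
                                tissue_columns = NULL) {
  structure(
    list(symbol_a = symbol_a, symbol_b = symbol_b, evidence = evidence,
         sources = sources, tissue_columns = tissue_columns),
    class = "interaction_dialect"
  )
}

EVIDENCE_RANK <- c(experimental = 1L, predicted = 2L, orthologous = 3L)

#' Read an interaction table
#'
#' Parses a tab-separated interaction table into canonical undirected edges:
#' symbols normalized, endpoints ordered lexicographically, duplicate rows
#' merged (source and tissue sets are unioned; on conflicting evidence the
#' strongest class wins, experimental > predicted > orthologous). Rows with
#' an empty symbol are skipped with a warning and counted. Self-loops are
#' retained and flagged; the network builder decides their fate.
#'
#' @param path path to the table. Lines starting with `#` are ignored.
#' @param dialect an [interaction_dialect()].
#' @return data.frame of class `interaction_edges` with columns `symbol_a`,
#'   `symbol_b`, `evidence`, `sources`, `tissues` (`;`-joined sets) and
#'   `is_selfloop`; attributes `n_skipped` and `n_deduplicated`.
#' @export
read_interactions <- function(path, dialect = interaction_dialect()) {
  stopifnot(inherits(dialect, "interaction_dialect"))
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  needed <- c(dialect$symbol_a, dialect$symbol_b, dialect$evidence,
              dialect$sources, dialect$tissue_columns)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    fail("interaction table is missing configured columns: ",
         paste(missing_cols, collapse = ", "))
  }
  a <- normalize_symbol(raw[[dialect$symbol_a]])
  b <- normalize_symbol(raw[[dialect$symbol_b]])
  keep <- nzchar(a) & nzchar(b)
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    warning(n_skipped, " interaction row(s) with an empty symbol skipped")
  }
  if (is.null(dialect$evidence)) {
    ev <- rep("experimental", length(a))
  } else {
    ev <- tolower(trimws(raw[[dialect$evidence]]))
    bad <- keep & !ev %in% EVIDENCE_TYPES
    if (any(bad)) {
      fail("row ", which(bad)[[1]], ": unknown evidence type '",
           ev[which(bad)[[1]]], "'")
    }
  }
  src <- if (is.null(dialect$sources)) rep("", length(a)) else {
    vapply(strsplit(raw[[dialect$sources]], "[;,]"),
           function(s) join_set(trimws(s)), character(1))
  }
  tis <- if (is.null(dialect$tissue_columns)) rep("", length(a)) else {
    flag <- sapply(dialect$tissue_columns, function(col) {
      tolower(trimws(raw[[col]])) %in% c("1", "y", "yes", "true")
    })
    flag <- matrix(flag, nrow = length(a))
    apply(flag, 1, function(f) join_set(dialect$tissue_columns[f]))
  }

  a2 <- pmin(a, b)
  b2 <- pmax(a, b)
  df <- data.frame(symbol_a = a2[keep], symbol_b = b2[keep],
                   evidence = ev[keep], sources = src[keep],
                   tissues = tis[keep], stringsAsFactors = FALSE)
  canonical_edges(df, n_skipped = n_skipped)
}

# Merge duplicate canonical pairs; attach bookkeeping attributes.
canonical_edges <- function(df, n_skipped = 0L) {
  if (nrow(df) == 0) {
    out <- data.frame(symbol_a = character(0), symbol_b = character(0),
                      evidence = character(0), sources = character(0),
                      tissues = character(0), is_selfloop = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    attr(out, "n_deduplicated") <- 0L
    class(out) <- c("interaction_edges", "data.frame")
    return(out)
  }
  key <- paste(df$symbol_a, df$symbol_b, sep = "\t")
  n_dup <- nrow(df) - length(unique(key))
  parts <- split(seq_len(nrow(df)), key)
  idx <- order(names(parts))
  parts <- parts[idx]
  merged <- lapply(parts, function(rows) {
    ev <- df$evidence[rows]
    data.frame(
      symbol_a = df$symbol_a[rows[[1]]],
      symbol_b = df$symbol_b[rows[[1]]],
      evidence = ev[which.min(EVIDENCE_RANK[ev])],
      sources = join_set(unlist(lapply(df$sources[rows], split_set))),
      tissues = join_set(unlist(lapply(df$tissues[rows], split_set))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out$is_selfloop <- out$symbol_a == out$symbol_b
  attr(out, "n_skipped") <- as.integer(n_skipped)
  attr(out, "n_deduplicated") <- as.integer(n_dup)
  class(out) <- c("interaction_edges", "data.frame")
  out
}

#' Write an interaction table in the package's canonical dialect
#'
#' Output re-reads via [read_interactions()] with the default dialect plus
#' `sources = "sources"`; tissue sets are stored as a `;`-joined column and
#' restored on re-read through the `tissues` passthrough column.
#'
#' @param edges an `interaction_edges` data.frame.
#' @param path output path.
#' @param header_comment optional comment line(s) written with a leading `#`
#'   (used by the synthetic generator to record its seed).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(edges, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines("symbol1\tsymbol2\tevidence_type\tsources\ttissues", con)
  if (nrow(edges)) {
    ord <- order(edges$symbol_a, edges$symbol_b)
    writeLines(paste(edges$symbol_a[ord], edges$symbol_b[ord],
                     edges$evidence[ord], edges$sources[ord],
                     edges$tissues[ord], sep = "\t"), con)
  }
  invisible(path)
}

# internal: re-read the canonical dialect including the tissues column
read_interactions_canonical <- function(path) {
  edges <- read_interactions(path, interaction_dialect(sources = "sources"))
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if ("tissues" %in% names(raw)) {
    a <- normalize_symbol(raw$symbol1); b <- normalize_symbol(raw$symbol2)
    key <- paste(pmin(a, b), pmax(a, b), sep = "\t")
    tmap <- tapply(raw$tissues, key, function(t) join_set(unlist(lapply(t, split_set))))
    edges$tissues <- unname(tmap[paste(edges$symbol_a, edges$symbol_b, sep = "\t")])
  }
  edges
}

#' Read an HPA-style protein expression table
#'
#' Expects tab-separated columns `symbol` (or `gene`), `tissue`, `level`.
#' Levels are folded to the four-level ordinal vocabulary `not_detected` <
#' `low` < `medium` < `high` (case-insensitive; spaces become underscores).
#' Duplicate (symbol, tissue) records are aggregated by maximum level.
#'
#' @param path path to the table (`#` comment lines ignored).
#' @param text literal text instead of a file.
#' @return data.frame of class `expression_table` with columns `symbol`,
#'   `tissue`, `level` (one row per symbol/tissue pair).
#' @export
read_expression <- function(path = NULL, text = NULL) {
  raw <- read_table_input(path, text, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "#")
  if (nrow(raw) == 0) {
    out <- data.frame(symbol = character(0), tissue = character(0),
                      level = character(0), stringsAsFactors = FALSE)
    class(out) <- c("expression_table", "data.frame")
    return(out)
  }
  sym_col <- intersect(c("symbol", "gene"), tolower(names(raw)))
  names(raw) <- tolower(names(raw))
  if (!length(sym_col) || !all(c("tissue", "level") %in% names(raw))) {
    fail("expression table needs columns symbol (or gene), tissue, level")
  }
  lvl <- gsub("[[:space:]]+", "_", tolower(trimws(raw$level)))
  bad <- which(!lvl %in% EXPRESSION_LEVELS)
  if (length(bad)) {
    fail("row ", bad[[1]], ": unknown expression level '", raw$level[bad[[1]]], "'")
  }
  df <- data.frame(
    symbol = normalize_symbol(raw[[sym_col[[1]]]]),
    tissue = tolower(trimws(raw$tissue)),
    level = lvl, stringsAsFactors = FALSE
  )
  ord <- match(df$level, EXPRESSION_LEVELS)
  key <- paste(df$symbol, df$tissue, sep = "\t")
  best <- tapply(ord, key, max)
  keys <- sort(names(best))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    symbol = vapply(parts, `[[`, character(1), 1),
    tissue = vapply(parts, `[[`, character(1), 2),
    level = EXPRESSION_LEVELS[best[keys]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Write an expression table
#' @param table an `expression_table`.
#' @param path output path.
#' @param header_comment optional `#` comment line(s).
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  writeLines("symbol\ttissue\tlevel", con)
  if (nrow(table)) {
    ord <- order(table$symbol, table$tissue)
    writeLines(paste(table$symbol[ord], table$tissue[ord], table$level[ord],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: each line is `term_id TAB description TAB member TAB
#' member ...`. Member symbols are normalized and deduplicated; a term with
#' no members after normalization is rejected, as is a duplicated term id.
#'
#' @param path path to the GMT file (`#` comment lines ignored).
#' @param source annotation source tag for every term in the file, from
#'   `GO_BP`, `KEGG`, `REACTOME`, `WIKIPATHWAYS`, `TF`, `MIRNA`.
#' @return data.frame of class `term_sets`: `term_id`, `term_name`,
#'   `source`, and list-column `members`.
#' @export
read_gmt <- function(path, source = "GO_BP") {
  if (!source %in% GMT_SOURCES) {
    fail("unknown annotation source '", source, "'; expected one of: ",
         paste(GMT_SOURCES, collapse = ", "))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  recs <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      fail("GMT line ", i, ": expected at least 3 tab-separated fields")
    }
    members <- sort(unique(normalize_symbol(parts[-(1:2)])))
    members <- members[nzchar(members)]
    if (!length(members)) fail("GMT line ", i, ": term has no members")
    list(term_id = trimws(parts[[1]]), term_name = trimws(parts[[2]]),
         members = members)
  })
  ids <- vapply(recs, `[[`, character(1), "term_id")
  if (anyDuplicated(ids)) {
    fail("duplicate term_id in GMT file: ", ids[duplicated(ids)][[1]])
  }
  out <- data.frame(
    term_id = ids,
    term_name = vapply(recs, `[[`, character(1), "term_name"),
    source = source, stringsAsFactors = FALSE
  )
  out$members <- lapply(recs, `[[`, "members")
  class(out) <- c("term_sets", "data.frame")
  out
}

#' Write a GMT gene-set collection
#' @param terms a `term_sets` data.frame.
#' @param path output path.
#' @param header_comment optional `#` comment line(s).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  if (nrow(terms)) {
    ord <- order(terms$term_id)
    for (i in ord) {
      writeLines(paste(c(terms$term_id[i], terms$term_name[i],
                         terms$members[[i]]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Export a network for Cytoscape
#'
#' Deterministic output: edges sorted by (symbol_a, symbol_b), nodes sorted
#' by symbol. `graphml` carries `gene_class` as a string node attribute;
#' `sif` (interaction type `pp`) and `tsv` write a `<path>.nodes.tsv`
#' sidecar with the node classes.
#'
#' @param network a `ppin`.
#' @param path output path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "ppin"))
  format <- tolower(format)
  format <- match.arg(format)
  nodes <- network$nodes[order(network$nodes$symbol), , drop = FALSE]
  e <- network$edges
  if (nrow(e)) e <- e[order(e$symbol_a, e$symbol_b), , drop = FALSE]

  if (format == "graphml") {
    xml_escape <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"d0\" for=\"node\" attr.name=\"gene_class\" attr.type=\"string\"/>",
      "  <key id=\"d1\" for=\"edge\" attr.name=\"evidence\" attr.type=\"string\"/>",
      "  <graph id=\"G\" edgedefault=\"undirected\">",
      sprintf("    <node id=\"%s\"><data key=\"d0\">%s</data></node>",
              xml_escape(nodes$symbol), nodes$node_class),
      if (nrow(e)) {
        sprintf("    <edge source=\"%s\" target=\"%s\"><data key=\"d1\">%s</data></edge>",
                xml_escape(e$symbol_a), xml_escape(e$symbol_b), e$evidence)
      },
      "  </graph>",
      "</graphml>"
    )
    writeLines(lines, path)
    return(invisible(path))
  }

  if (format == "sif") {
    lines <- if (nrow(e)) paste(e$symbol_a, "pp", e$symbol_b, sep = "\t") else character(0)
    connected <- unique(c(e$symbol_a, e$symbol_b))
    isolated <- setdiff(nodes$symbol, connected)
    writeLines(c(lines, isolated), path)
  } else {
    con <- file(path, "w")
    writeLines("symbol_a\tsymbol_b\tevidence\tsources\ttissues", con)
    if (nrow(e)) {
      writeLines(paste(e$symbol_a, e$symbol_b, e$evidence, e$sources,
                       e$tissues, sep = "\t"), con)
    }
    close(con)
  }
  side <- paste0(path, ".nodes.tsv")
  con <- file(side, "w")
  writeLines("symbol\tgene_class", con)
  if (nrow(nodes)) writeLines(paste(nodes$symbol, nodes$node_class, sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Read a TSV edge-list export back into a network
#'
#' Inverse of [write_graph_file()] with `format = "tsv"`: reads the edge
#' list and, when present, the `<path>.nodes.tsv` sidecar with node classes.
#'
#' @param path path written by [write_graph_file()].
#' @return a `ppin`.
#' @export
read_graph_tsv <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  edges <- data.frame(
    symbol_a = e$symbol_a %||% character(0),
    symbol_b = e$symbol_b %||% character(0),
    evidence = e$evidence %||% character(0),
    sources = e$sources %||% character(0),
    tissues = e$tissues %||% character(0),
    stringsAsFactors = FALSE
  )
  side <- paste0(path, ".nodes.tsv")
  if (file.exists(side)) {
    nd <- utils::read.delim(side, stringsAsFactors = FALSE, colClasses = "character")
    nodes <- data.frame(symbol = nd$symbol, node_class = nd$gene_class,
                        stringsAsFactors = FALSE)
  } else {
    syms <- sort(unique(c(edges$symbol_a, edges$symbol_b)))
    nodes <- data.frame(symbol = syms, node_class = "INTERACTOR",
                        stringsAsFactors = FALSE)
  }
  new_ppin(nodes, edges)
}
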