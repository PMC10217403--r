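# Internal helpers shared across modules.

GENE_CLASSES <- c("RTT_CLASSICAL", "RTT_ATYPICAL", "RTTL_COHORT", "RTTL_LITERATURE")
NODE_CLASSES <- c("RTT_SEED", "RTTL_SEED", "INTERACTOR")
EVIDENCE_TYPES <- c("experimental", "predicted", "orthologous")
EXPRESSION_LEVELS <- c("not_detected", "low", "medium", "high")
GMT_SOURCES <- c("GO_BP", "KEGG", "REACTOME", "WIKIPATHWAYS", "TF", "MIRNA")

#' Normalize gene symbols
#'
#' Uppercases, trims surrounding whitespace and removes internal whitespace.
#' No alias or HGNC resolution is attempted: the analysis works at the symbol
#' level, exactly as printed in its source tables.
#'
#' @param x character vector of raw symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_symbol(c(" tcf4", "Mecp2 "))
#' @export
normalize_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", "", x)
}

# stop() with a consistent prefix, no call echo
fail <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb an outer simulation stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Split a ";"-joined set field back into a sorted character set.
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(strsplit(x, ";", fixed = TRUE)[[1]]))
}

join_set <- function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";")

# read a delimited table given either a path or literal text
read_table_input <- function(file = NULL, text = NULL, ...) {
  if (is.null(file) && is.null(text)) fail("either `file` or `text` must be given")
  if (!is.null(text)) {
    utils::read.delim(text = text, ...)
  } else {
    if (!file.exists(file)) fail("file not found: ", file)
    utils::read.delim(file, ...)
  }
}
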