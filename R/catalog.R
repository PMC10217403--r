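# Seed-gene catalogs: curated RTT / RTT-L gene lists and the cohort
# phenotype table, with per-patient diagnostic-criteria tabulation.

new_gene_catalog <- function(records) {
  records <- records[!duplicated(records[c("symbol", "gene_class")]), , drop = FALSE]
  records <- records[order(records$gene_class, records$symbol), , drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(
      records = records,
      n_rtt = length(rtt_symbols_df(records)),
      n_rttl = length(rttl_symbols_df(records))
    ),
    class = "gene_catalog"
  )
}

rtt_symbols_df <- function(records) {
  sort(unique(records$symbol[records$gene_class %in% c("RTT_CLASSICAL", "RTT_ATYPICAL")]))
}

rttl_symbols_df <- function(records) {
  sort(unique(records$symbol[records$gene_class %in% c("RTTL_COHORT", "RTTL_LITERATURE")]))
}

#' Distinct RTT seed symbols (classical plus atypical) in a catalog
#' @param catalog a `gene_catalog`.
#' @return sorted character vector.
#' @export
rtt_symbols <- function(catalog) rtt_symbols_df(catalog$records)

#' Distinct RTT-L seed symbols (cohort plus literature) in a catalog
#' @param catalog a `gene_catalog`.
#' @return sorted character vector.
#' @export
rttl_symbols <- function(catalog) rttl_symbols_df(catalog$records)

#' All distinct seed symbols in a catalog
#' @param catalog a `gene_catalog`.
#' @return sorted character vector.
#' @export
seed_symbols <- function(catalog) {
  sort(unique(catalog$records$symbol))
}

#' Parse a curated seed-gene list
#'
#' Reads the two-column tab-separated seed-list dialect: one row per gene
#' class, `class_label` TAB comma-separated symbols. Class labels come from
#' the closed vocabulary `RTT_CLASSICAL`, `RTT_ATYPICAL`, `RTTL_COHORT`,
#' `RTTL_LITERATURE`. Symbols are normalized ([normalize_symbol()]) and
#' deduplicated within a class; a symbol may legitimately belong to several
#' classes (TCF4, for example, is both a cohort and a literature RTT-L gene).
#'
#' @param file path to the seed-list file; the packaged curated lists live at
#'   `system.file("extdata", "table2_seed_lists.tsv", package = "rettnet")`.
#' @param text literal text instead of a file.
#' @param provenance free-text provenance tag stored on every record.
#' @return a `gene_catalog`: list with `records` (data.frame of `symbol`,
#'   `gene_class`, `provenance`), `n_rtt` (distinct classical + atypical
#'   symbols) and `n_rttl` (distinct cohort + literature symbols).
#' @examples
#' cat <- parse_catalog(system.file("extdata", "table2_seed_lists.tsv",
#'   package = "rettnet"))
#' cat$n_rtt
#' @export
parse_catalog <- function(file = NULL, text = NULL, provenance = "curated") {
  if (is.null(file) && is.null(text)) fail("either `file` or `text` must be given")
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]] else {
    if (!file.exists(file)) fail("file not found: ", file)
    readLines(file)
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("^class_label\t", lines[[1]])) lines <- lines[-1]
  if (!length(lines)) fail("seed list is empty")

  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) fail("row ", i, ": expected `class_label<TAB>symbols`")
    label <- trimws(parts[[1]])
    if (!label %in% GENE_CLASSES) {
      fail("row ", i, ": unknown class label '", label, "'")
    }
    syms <- normalize_symbol(strsplit(parts[[2]], ",", fixed = TRUE)[[1]])
    if (any(!nzchar(syms))) fail("row ", i, ": empty gene symbol")
    recs[[i]] <- data.frame(
      symbol = syms, gene_class = label, provenance = provenance,
      stringsAsFactors = FALSE
    )
  }
  new_gene_catalog(do.call(rbind, recs))
}

#' Serialize a seed-gene catalog to its input dialect
#'
#' Writes one row per class present, so `parse_catalog(write_catalog(x))`
#' round-trips to an identical catalog.
#'
#' @param catalog a `gene_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  rec <- catalog$records
  classes <- GENE_CLASSES[GENE_CLASSES %in% rec$gene_class]
  lines <- c("class_label\tsymbols", vapply(classes, function(cl) {
    paste0(cl, "\t", paste(sort(unique(rec$symbol[rec$gene_class == cl])), collapse = ", "))
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Combine cohort and literature RTT-L catalogs
#'
#' Takes the union by symbol across the RTT-L classes. Membership in both
#' classes is preserved as two records; the overlap (symbols present in both
#' inputs' RTT-L lists) is reported so the caller can see how the distinct
#' count relates to the two input sizes. Any RTT-class records present in
#' either input are carried through unchanged.
#'
#' @param cohort,literature `gene_catalog` objects.
#' @return a `gene_catalog` with an extra element `overlap`: the sorted
#'   symbols shared by the two RTT-L lists.
#' @export
combine_rttl <- function(cohort, literature) {
  stopifnot(inherits(cohort, "gene_catalog"), inherits(literature, "gene_catalog"))
  combined <- new_gene_catalog(rbind(cohort$records, literature$records))
  combined$overlap <- intersect(rttl_symbols(cohort), rttl_symbols(literature))
  combined
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("Seed-gene catalog:", nrow(x$records), "records\n")
  cat("  distinct RTT symbols:  ", x$n_rtt, "\n")
  cat("  distinct RTT-L symbols:", x$n_rttl, "\n")
  tab <- table(x$records$gene_class)
  for (cl in names(tab)) cat(sprintf("  %-16s %d\n", cl, tab[[cl]]))
  if (!is.null(x$overlap)) {
    cat("  RTT-L overlap:", paste(x$overlap, collapse = ", "), "\n")
  }
  invisible(x)
}

PHENOTYPE_COLUMNS <- c(
  "Developmental Regression", "Developmental Delay", "Intellectual Disability",
  "Microcephaly", "Loss of Hand Use", "Stereotyped Hand Movements",
  "Involuntary Tongue Movements", "Hyperventilation", "Choreoathetosis",
  "Early Epileptic Encephalopathy", "Hypotonia", "Scoliosis"
)

#' Parse the cohort phenotype/variant table
#'
#' Reads the tab-separated clinical table: one row per patient with the 12
#' phenotype columns flagged Y/N, the mutated gene, variant descriptors, and
#' the CADD PHRED score (stored as data, never computed).
#'
#' @param file path to the table; the packaged cohort table is at
#'   `system.file("extdata", "table1_patients.tsv", package = "rettnet")`.
#' @param text literal text instead of a file.
#' @return a data.frame of class `patient_table`: `patient_id`, one logical
#'   column per phenotype, `gene` (normalized), `variant_coord`,
#'   `cdna_change`, `protein_change`, `cadd_phred`. The phenotype column
#'   names are kept verbatim and recorded in `attr(, "phenotype_cols")`.
#' @export
parse_patients <- function(file = NULL, text = NULL) {
  raw <- read_table_input(file, text,
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  missing_cols <- setdiff(c("Patient", PHENOTYPE_COLUMNS, "Gene"), names(raw))
  if (length(missing_cols)) {
    fail("patient table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    out <- data.frame(patient_id = integer(0))
    for (ph in PHENOTYPE_COLUMNS) out[[ph]] <- logical(0)
    out$gene <- character(0)
    out$cadd_phred <- numeric(0)
    attr(out, "phenotype_cols") <- PHENOTYPE_COLUMNS
    class(out) <- c("patient_table", "data.frame")
    return(out)
  }
  flags <- lapply(PHENOTYPE_COLUMNS, function(col) {
    v <- trimws(raw[[col]])
    bad <- which(!v %in% c("Y", "N"))
    if (length(bad)) {
      fail("row ", bad[[1]], ", column '", col, "': flag must be Y or N, got '",
           v[bad[[1]]], "'")
    }
    v == "Y"
  })
  names(flags) <- PHENOTYPE_COLUMNS
  out <- data.frame(patient_id = as.integer(raw$Patient), check.names = FALSE)
  for (ph in PHENOTYPE_COLUMNS) out[[ph]] <- flags[[ph]]
  out$gene <- normalize_symbol(raw$Gene)
  out$variant_coord <- trimws(raw[["Variant: Genomic Coordinates"]] %||% NA_character_)
  out$cdna_change <- trimws(raw[["cDNA Change"]] %||% NA_character_)
  out$protein_change <- trimws(raw[["Protein Change"]] %||% NA_character_)
  out$cadd_phred <- as.numeric(raw[["CADD PHRED Score"]] %||% NA)
  attr(out, "phenotype_cols") <- PHENOTYPE_COLUMNS
  class(out) <- c("patient_table", "data.frame")
  out
}

#' Default mapping of main diagnostic criteria to phenotype columns
#'
#' The consortium main criteria are regression, loss of purposeful hand
#' skills, loss of spoken language, gait abnormalities, and hand
#' stereotypies. The cohort table carries columns for only three of these;
#' the mapping deliberately covers just those three rather than inventing
#' phenotype data for the rest (there is no spoken-language or gait column).
#'
#' @return named character vector: criterion name -> phenotype column.
#' @export
default_criteria_map <- function() {
  c(
    "regression" = "Developmental Regression",
    "loss of hand use" = "Loss of Hand Use",
    "hand stereotypies" = "Stereotyped Hand Movements"
  )
}

#' Tabulate main diagnostic criteria per patient
#'
#' Counts, for each patient, how many of the mapped main criteria are
#' flagged present, and reports how often each criterion occurs across the
#' cohort.
#'
#' @param patients a `patient_table` from [parse_patients()].
#' @param criteria_map named character vector mapping criterion names to
#'   phenotype columns; defaults to [default_criteria_map()].
#' @return list with `profiles` (data.frame: `patient_id`,
#'   `n_main_criteria_met`), `criteria_used` (criterion names) and
#'   `frequency` (named integer: patients positive per criterion).
#' @export
tabulate_criteria <- function(patients, criteria_map = default_criteria_map()) {
  stopifnot(inherits(patients, "patient_table"))
  unmapped <- setdiff(unname(criteria_map), names(patients))
  if (length(unmapped)) {
    fail("criteria map names missing columns: ", paste(unmapped, collapse = ", "))
  }
  if (length(criteria_map) == 0) {
    counts <- rep(0L, nrow(patients))
    freq <- integer(0)
  } else {
    mat <- sapply(unname(criteria_map), function(col) patients[[col]])
    mat <- matrix(mat, nrow = nrow(patients))
    counts <- as.integer(rowSums(mat))
    freq <- as.integer(colSums(mat))
    names(freq) <- names(criteria_map)
  }
  list(
    profiles = data.frame(
      patient_id = patients$patient_id,
      n_main_criteria_met = counts
    ),
    criteria_used = names(criteria_map),
    frequency = freq
  )
}
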