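# Readers/writers: FASTA sequence sets, the tabular formats the pipeline
# consumes (annotation maps, ontology edges, external alignment results),
# run configuration, and config-stamped TSV reports.

IUPAC_NT <- c(
  "A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"
)

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`; IUPAC ambiguity
#' codes are kept (they translate to `X` downstream unless all resolutions
#' agree). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `description` (one row per
#'   record).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- chartr("u", "t", tolower(as.character(set)))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    abort(paste0("empty sequence for id(s): ",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  bad <- regexpr(paste0("[^", paste(IUPAC_NT, collapse = ""), "]"), seqs)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    abort(sprintf(
      "illegal character '%s' at position %d of sequence '%s'",
      substr(seqs[k], bad[k], bad[k]), bad[k], ids[k]
    ))
  }
  tibble(id = ids, seq = unname(seqs), description = unname(desc))
}

#' Write sequence records to FASTA
#'
#' @param records A tibble with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  if (is.null(records[["description"]])) desc <- rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[k])) paste(records$id[k], desc[k]) else records$id[k]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = character())
}

#' Read a gene-to-function annotation table
#'
#' Expects tab-separated columns `gene_id`, `fun`, `category`, `evalue`
#' (the shape a KOG-style domain-search report reduces to).
#'
#' @param path Path to a TSV file.
#' @return A typed tibble.
#' @export
read_gene_function_table <- function(path) {
  tbl <- read_tsv_quiet(path, readr::cols(
    gene_id = readr::col_character(), fun = readr::col_character(),
    category = readr::col_character(), evalue = readr::col_double()
  ))
  check_evalues(tbl$evalue, path)
  tbl
}

#' Read a gene-to-ontology-term annotation table
#'
#' Columns `gene_id`, `term`, and optionally `protein_name`, `evalue`.
#'
#' @param path Path to a TSV file.
#' @return A typed tibble.
#' @export
read_gene_term_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), term = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  if (!is.null(tbl$evalue)) check_evalues(tbl$evalue, path)
  tbl
}

#' Read an ontology edge list
#'
#' Tab-separated `parent`, `child` term pairs, optionally with a `label`
#' column naming the child term.
#'
#' @param path Path to a TSV file.
#' @return A typed tibble of edges.
#' @export
read_ontology_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    parent = readr::col_character(), child = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
}

check_evalues <- function(evalue, what) {
  bad <- which(!is.na(evalue) & evalue <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive evalue at data row(s) %s of %s",
                  paste(head(bad, 5), collapse = ", "), what))
  }
  invisible(TRUE)
}

ALIGNMENT_COLS <- c(
  "query_id", "subject_id", "pct_identity", "length", "mismatch", "gapopen",
  "query_start", "query_end", "subject_start", "subject_end", "evalue",
  "score", "aligned_query", "aligned_subject"
)

#' Read external homology-search results
#'
#' BLAST-style 12-column tabular output extended with two
#' aligned-sequence-string columns (`aligned_query`, `aligned_subject`).
#' Rows with unequal aligned-string lengths or non-positive E-values are
#' rejected with their line numbers.
#'
#' @param path Path to a TSV file with header.
#' @return A typed tibble of alignment records.
#' @export
read_alignment_table <- function(path) {
  tbl <- read_tsv_quiet(path, readr::cols(
    query_id = readr::col_character(), subject_id = readr::col_character(),
    aligned_query = readr::col_character(),
    aligned_subject = readr::col_character(),
    evalue = readr::col_double(), score = readr::col_double(),
    .default = readr::col_integer()
  ))
  missing <- setdiff(ALIGNMENT_COLS, names(tbl))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(nchar(tbl$aligned_query) != nchar(tbl$aligned_subject))
  if (length(bad)) {
    abort(sprintf("aligned strings differ in length at data row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  check_evalues(tbl$evalue, path)
  tbl
}

#' Pipeline run configuration
#'
#' Houses every threshold the pipeline applies, plus the random seed.
#' Defaults are the published operating point: homolog pairs are kept when
#' the query is at least 600 nt long, the pair E-value is at most 1e-30 and
#' the conserved region spans at least 80 nt; the ranked list is split at
#' its top and bottom 15%; functional classification requires an annotation
#' E-value strictly below 1e-10.
#'
#' @param min_query_len_nt Minimum query unigene length (nt).
#' @param max_evalue_pair E-value ceiling for a homolog pair.
#' @param min_region_nt Minimum conserved-region span (nt).
#' @param split_fraction Fraction taken from each end of the ranked list;
#'   must lie strictly between 0 and 0.5.
#' @param max_evalue_function Annotation E-value ceiling (strict `<`).
#' @param max_evalue_conservation Named numeric vector of per-dataset
#'   E-value ceilings for conservation calling.
#' @param seed Integer random seed recorded in every report header.
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_query_len_nt = 600L, max_evalue_pair = 1e-30,
                       min_region_nt = 80L, split_fraction = 0.15,
                       max_evalue_function = 1e-10,
                       max_evalue_conservation = c(default = 1e-10),
                       seed = 1L) {
  if (!(split_fraction > 0 && split_fraction < 0.5)) {
    abort("split_fraction must lie strictly between 0 and 0.5")
  }
  if (min_query_len_nt < 1 || min_region_nt < 1 ||
      min_query_len_nt != round(min_query_len_nt) ||
      min_region_nt != round(min_region_nt)) {
    abort("length thresholds must be positive integers")
  }
  structure(
    list(
      min_query_len_nt = as.integer(min_query_len_nt),
      max_evalue_pair = max_evalue_pair,
      min_region_nt = as.integer(min_region_nt),
      split_fraction = split_fraction,
      max_evalue_function = max_evalue_function,
      max_evalue_conservation = max_evalue_conservation,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a flat key=value run configuration file
#'
#' @param path Path to a `key=value` file (one pair per line; `#` comments
#'   allowed).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- trimws(vapply(kv, `[`, "", 1))
  do.call(run_config, vals)
}

config_header <- function(config) {
  flat <- unlist(config)
  paste0("# ", names(flat), " = ", vapply(flat, format, ""))
}

#' Write a config-stamped TSV report
#'
#' Every report the pipeline emits carries the full run-configuration
#' snapshot (thresholds and seed) as `# key = value` header lines, so the
#' operating point of any result file is auditable.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @param config The [run_config()] used to produce `tbl`.
#' @return `path`, invisibly.
#' @export
write_report <- function(tbl, path, config) {
  stopifnot(inherits(config, "run_config"))
  con <- file(path, "w")
  writeLines(config_header(config), con)
  close(con)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a config-stamped TSV report
#'
#' @param path Path written by [write_report()].
#' @return A tibble with the parsed config snapshot attached as attribute
#'   `"config"` (a named character vector).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), " = ", fixed = TRUE)
  cfg <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tbl <- readr::read_tsv(I(lines[!startsWith(lines, "# ")]),
                         col_types = readr::cols(), progress = FALSE)
  attr(tbl, "config") <- cfg
  tbl
}

#' Load the packaged CNS-development gene-set table
#'
#' A 96-row gene-by-subcategory table of planarian central-nervous-system
#' development genes with per-dataset presence marks for the
#' *S. mediterranea* genome/transcriptome and the schistosome
#' genome/transcriptome, transcribed cell-for-cell from the published
#' comparison. Presence is `"+"`, absence the empty string. One E-value is
#' recorded as `0` — a search-tool underflow of a vanishingly small value —
#' so this loader alone accepts `evalue >= 0`.
#'
#' @return A tibble with columns `subcategory`, `unigene_id`,
#'   `protein_name`, `evalue`, `smed_genome`, `smed_mrna`,
#'   `schisto_genome`, `schisto_mrna`.
#' @export
load_cns_gene_set <- function() {
  path <- system.file("extdata", "cns_gene_set_table.tsv",
                      package = "matchratio", mustWork = TRUE)
  tbl <- read_tsv_quiet(path, readr::cols(
    evalue = readr::col_double(), .default = readr::col_character()
  ))
  stopifnot(all(tbl$evalue >= 0))
  tbl
}

#' Load the packaged EST library summary table
#'
#' Per-library sequencing yields of the planarian head/eye EST project:
#' valid 5'- and 3'-end read counts, paired-assembly (overlap) contigs
#' and gap-closed full-insert sequences, transcribed from the published
#' summary. The Eye-library and first Head-library 5' entries are
#' previously registered archive reads folded into the assembly.
#'
#' @return A tibble with one row per library series.
#' @export
load_est_library_table <- function() {
  path <- system.file("extdata", "est_library_table.tsv",
                      package = "matchratio", mustWork = TRUE)
  read_tsv_quiet(path, readr::cols(
    library = readr::col_character(), prefix = readr::col_character(),
    plates = readr::col_character(), sequencer = readr::col_character(),
    .default = readr::col_integer()
  ))
}

#' Load the packaged assembly summary table
#'
#' Per-class unigene counts and total bases of the published de novo
#' assembly, with the printed mean/median lengths alongside for
#' comparison. Means recomputed as `total_bases / n` are the quantity of
#' record; the printed singleton and all-class means are internally
#' inconsistent with the printed totals.
#'
#' @return A tibble with rows `contigs`, `singletons`, `all`.
#' @export
load_assembly_summary <- function() {
  path <- system.file("extdata", "assembly_summary_table.tsv",
                      package = "matchratio", mustWork = TRUE)
  tbl <- read_tsv_quiet(path, readr::cols(
    class = readr::col_character(), .default = readr::col_double()
  ))
  mutate(tbl, mean_length = .data$total_bases / .data$n)
}
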