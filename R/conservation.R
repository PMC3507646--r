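# Presence/absence conservation calls: the OR rule over homology-search
# channels, and gene-set-level conservation summaries.

#' Call per-dataset gene conservation with the OR rule
#'
#' A gene is called present (evolutionarily conserved) in a dataset iff at
#' least one search channel's E-value passes that dataset's ceiling
#' (`evalue <= threshold`; smaller is stronger). Genes with no passing
#' evidence — or no evidence at all — are absent. The winning channel and
#' its E-value are retained for audit.
#'
#' @param evidence Tibble (`gene_id`, `dataset`, `channel`, `evalue`).
#' @param thresholds Named numeric vector: one E-value ceiling per
#'   dataset. Evidence referencing a dataset without a threshold is an
#'   error.
#' @param genes Optional character vector fixing the gene universe;
#'   defaults to the genes seen in `evidence`.
#' @return A tibble of class `conservation_matrix`: one row per
#'   gene-dataset cell with `present`, `best_channel`, `best_evalue`.
#' @export
call_conservation <- function(evidence, thresholds, genes = NULL) {
  unknown <- setdiff(unique(evidence$dataset), names(thresholds))
  if (length(unknown)) {
    abort(paste0("evidence references unknown dataset(s): ",
                 paste(unknown, collapse = ", ")))
  }
  genes <- genes %||% unique(evidence$gene_id)
  grid <- tidyr::expand_grid(gene_id = genes, dataset = names(thresholds))
  ev <- mutate(evidence,
               pass = .data$evalue <= unname(thresholds[.data$dataset]))
  ev <- ev[order(ev$evalue), ]
  best <- ev[ev$pass, ]
  best <- best[!duplicated(best[, c("gene_id", "dataset")]), ]
  out <- left_join(
    grid,
    select(best, "gene_id", "dataset",
           best_channel = "channel", best_evalue = "evalue"),
    by = c("gene_id", "dataset")
  )
  out$present <- !is.na(out$best_evalue)
  class(out) <- c("conservation_matrix", class(out))
  out
}

#' Convert presence marks of a gene-set table to a conservation matrix
#'
#' Reads `"+"`/empty presence columns (the published table's rendering)
#' into the long gene-by-dataset form used by [summarize_matrix()]. A gene
#' marked present in any of its subcategory rows is present in that
#' dataset.
#'
#' @param gene_set_table A tibble with a gene id column (`gene_id` or
#'   `unigene_id`) and one `"+"`/empty column per dataset.
#' @param dataset_cols Character vector naming the presence columns.
#' @return A `conservation_matrix` tibble (`gene_id`, `dataset`,
#'   `present`).
#' @export
marks_to_matrix <- function(gene_set_table,
                            dataset_cols = c("smed_genome", "smed_mrna",
                                             "schisto_genome", "schisto_mrna")) {
  id_col <- if ("gene_id" %in% names(gene_set_table)) "gene_id" else "unigene_id"
  long <- tidyr::pivot_longer(
    gene_set_table[, c(id_col, dataset_cols)],
    all_of(dataset_cols), names_to = "dataset", values_to = "mark"
  )
  out <- summarise(
    group_by(long, gene_id = .data[[id_col]], .data$dataset),
    present = any(.data$mark == "+"), .groups = "drop"
  )
  class(out) <- c("conservation_matrix", class(out))
  out
}

#' Summarize a conservation matrix over a gene set
#'
#' For every dataset column: the number of distinct gene-set genes called
#' present, the fraction of the set, and the whole-percent rendering
#' (91% style); plus a per-subcategory breakdown. A gene present in any
#' subcategory row counts once per dataset.
#'
#' @param matrix A [call_conservation()] / [marks_to_matrix()] result.
#' @param gene_set_table A gene-set table (`subcategory` + gene id
#'   column); every gene must appear in the matrix.
#' @return A list with `per_dataset` (tibble `dataset`, `present`,
#'   `total`, `fraction`, `percent`) and `per_subcategory` (tibble
#'   `subcategory`, `dataset`, `present`, `total`).
#' @examples
#' tbl5 <- load_cns_gene_set()
#' summarize_matrix(marks_to_matrix(tbl5), tbl5)$per_dataset
#' @export
summarize_matrix <- function(matrix, gene_set_table) {
  id_col <- if ("gene_id" %in% names(gene_set_table)) "gene_id" else "unigene_id"
  genes <- unique(gene_set_table[[id_col]])
  missing <- setdiff(genes, matrix$gene_id)
  if (length(missing)) {
    abort(paste0("gene-set gene(s) missing from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  cells <- filter(matrix, .data$gene_id %in% genes)
  per_dataset <- summarise(
    group_by(cells, .data$dataset),
    present = sum(.data$present), total = length(genes),
    .groups = "drop"
  )
  per_dataset <- mutate(per_dataset,
                        fraction = .data$present / .data$total,
                        percent = round(100 * .data$fraction))
  membership <- distinct(tibble(
    subcategory = gene_set_table$subcategory,
    gene_id = gene_set_table[[id_col]]
  ))
  per_sub <- summarise(
    group_by(
      left_join(membership, cells, by = "gene_id",
                relationship = "many-to-many"),
      .data$subcategory, .data$dataset
    ),
    present = sum(.data$present), total = dplyr::n(), .groups = "drop"
  )
  list(per_dataset = per_dataset, per_subcategory = per_sub)
}
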