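# Ontology-driven gene-set extraction: descendant roll-up over an edge
# list, duplicate-aware gene-by-subcategory tables, and their counting.

#' Map every descendant term to its root subcategory
#'
#' Computes, for each root subcategory, the set of terms reachable from it
#' in the parent-to-child ontology graph (including the root itself).
#' Terms reachable from several roots map to all of them. The edge list
#' must be acyclic.
#'
#' @param edges Tibble (`parent`, `child`) of ontology edges.
#' @param subcategory_roots Character vector of root terms.
#' @return A tibble (`term`, `root`) — one row per (term, root) pair.
#' @export
rollup_descendants <- function(edges, subcategory_roots) {
  g <- igraph::graph_from_data_frame(
    edges[, c("parent", "child")], directed = TRUE,
    vertices = unique(c(edges$parent, edges$child, subcategory_roots))
  )
  if (!igraph::is_dag(g)) abort("cycle detected in ontology edge list")
  purrr::map_dfr(subcategory_roots, function(root) {
    reach <- igraph::subcomponent(g, root, mode = "out")
    tibble(term = names(reach), root = root)
  })
}

#' Extract a gene set from term annotations with descendant roll-up
#'
#' A gene annotated with any term that rolls up to a root subcategory
#' yields one row per (gene, root subcategory) pair — a multifunctional
#' gene therefore appears once per subcategory it reaches, and the total
#' match count exceeds the distinct-gene count by exactly those
#' duplications. Rows are ordered by subcategory, then input order.
#'
#' @param gene_terms Tibble (`gene_id`, `term`), optionally with
#'   `protein_name` and `evalue` metadata carried through.
#' @param rollup_map A [rollup_descendants()] result.
#' @return A tibble of class `gene_set_table` (`subcategory`, `gene_id`,
#'   plus any carried metadata).
#' @export
extract_gene_set <- function(gene_terms, rollup_map) {
  hit <- dplyr::inner_join(gene_terms, rollup_map,
                           by = c(term = "term"),
                           relationship = "many-to-many")
  hit <- rename(hit, subcategory = "root")
  keep <- intersect(c("subcategory", "gene_id", "protein_name", "evalue"),
                    names(hit))
  out <- distinct(select(hit, all_of(keep)),
                  .data$subcategory, .data$gene_id, .keep_all = TRUE)
  out <- out[order(out$subcategory), ]
  class(out) <- c("gene_set_table", class(out))
  out
}

#' Count matches and distinct genes in a gene-set table
#'
#' Matches are rows (one per gene-subcategory assignment); distinct genes
#' count each gene once however many subcategories it reaches.
#'
#' @param gene_set_table A tibble with `subcategory` and either
#'   `gene_id` or `unigene_id` columns (the packaged fixture uses the
#'   latter).
#' @return A list with `per_subcategory` (tibble `subcategory`,
#'   `matches`), `total_matches` and `distinct_genes`.
#' @examples
#' count_matches_and_genes(load_cns_gene_set())
#' @export
count_matches_and_genes <- function(gene_set_table) {
  id_col <- if ("gene_id" %in% names(gene_set_table)) "gene_id" else "unigene_id"
  per <- dplyr::count(gene_set_table, .data$subcategory, name = "matches")
  per <- arrange(per, dplyr::desc(.data$matches))
  list(
    per_subcategory = per,
    total_matches = nrow(gene_set_table),
    distinct_genes = dplyr::n_distinct(gene_set_table[[id_col]])
  )
}
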