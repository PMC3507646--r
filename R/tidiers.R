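# broom-style tidiers for the pipeline's result objects.

#' Tidy a split result
#'
#' One row per selected gene with its substitution class.
#'
#' @param x A [rank_and_split()] result.
#' @param ... Unused.
#' @return A tibble with `query_id`, `ratio`, `class`.
#' @export
tidy.split_result <- function(x, ...) {
  bind_rows(
    mutate(x$high_substitution, class = "high_substitution"),
    mutate(x$low_substitution, class = "low_substitution")
  )
}

#' One-row summary of a split result
#'
#' @param x A [rank_and_split()] result.
#' @param ... Unused.
#' @return A tibble with `n_total`, `n_per_side`, `n_selected` and the
#'   ratio range of each side.
#' @export
glance.split_result <- function(x, ...) {
  tibble(
    n_total = x$n_total, n_per_side = x$n_per_side,
    n_selected = 2L * x$n_per_side,
    max_high_ratio = max(x$high_substitution$ratio),
    min_low_ratio = min(x$low_substitution$ratio)
  )
}

#' Tidy a function table
#'
#' @param x A [classify_by_function()] / [log2_odds_table()] result.
#' @param ... Unused.
#' @return The underlying tibble with log2 odds filled.
#' @export
tidy.function_table <- function(x, ...) {
  out <- if (is.null(x[["log2_odds"]])) log2_odds_table(x) else x
  as_tibble(out)
}

#' One-row summary of a function table
#'
#' @param x A function table.
#' @param ... Unused.
#' @return A tibble with function/gene totals, the finite log2-odds range
#'   and the number of single-class functions.
#' @export
glance.function_table <- function(x, ...) {
  t <- tidy.function_table(x)
  fin <- t$log2_odds[is.finite(t$log2_odds)]
  tibble(
    n_functions = nrow(t),
    n_genes = sum(t$conserved_count) + sum(t$identical_count),
    n_all_one_class = sum(t$all_one_class),
    log2_odds_max = if (length(fin)) max(fin) else NA_real_,
    log2_odds_min = if (length(fin)) min(fin) else NA_real_
  )
}

#' Tidy an accumulation curve
#'
#' @param x An [accumulation_curve()] result.
#' @param ... Unused.
#' @return Per-size mean and spread of the non-redundant cluster count.
#' @export
tidy.accumulation_curve <- function(x, ...) {
  summarise(
    group_by(as_tibble(x), .data$sample_size),
    mean_clusters = mean(.data$clusters),
    sd_clusters = stats::sd(.data$clusters),
    min_clusters = min(.data$clusters),
    max_clusters = max(.data$clusters),
    replicates = dplyr::n(),
    .groups = "drop"
  )
}

#' One-row summary of a conservation matrix
#'
#' @param x A [call_conservation()] result.
#' @param ... Unused.
#' @return A tibble with cell, gene and dataset totals and the overall
#'   presence fraction.
#' @export
glance.conservation_matrix <- function(x, ...) {
  tibble(
    n_genes = dplyr::n_distinct(x$gene_id),
    n_datasets = dplyr::n_distinct(x$dataset),
    n_present = sum(x$present),
    fraction_present = mean(x$present)
  )
}
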