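# Ranking pairs by identical match ratio, extracting the high/low
# substitution extremes, functional classification, and the log2
# conserved/identical odds table.

#' Split ranked pairs into high- and low-substitution extremes
#'
#' Pairs are stably sorted ascending by (ratio, query id). The first
#' `floor(split_fraction * n)` queries — the lowest identical match
#' ratios — form the high-substitution ("conserved protein") class; the
#' last as many form the low-substitution ("identical protein") class.
#'
#' @param pairs A tibble with defined `ratio` and `query_id` columns.
#' @param split_fraction Fraction per side, strictly between 0 and 0.5.
#' @return A list of class `split_result`: `high_substitution` and
#'   `low_substitution` gene tibbles, `n_total`, `n_per_side`.
#' @examples
#' pairs <- tibble::tibble(query_id = sprintf("g%02d", 1:10),
#'                         ratio = seq(0.5, 0.95, length.out = 10))
#' rank_and_split(pairs, 0.15)$n_per_side # 1
#' @export
rank_and_split <- function(pairs, split_fraction = 0.15) {
  if (!(split_fraction > 0 && split_fraction < 0.5)) {
    abort("split_fraction must lie strictly between 0 and 0.5")
  }
  if (any(is.na(pairs$ratio))) {
    abort("all pairs must have a defined identical match ratio")
  }
  n_total <- nrow(pairs)
  n_side <- floor(split_fraction * n_total)
  if (n_side == 0) {
    abort("split_fraction * n yields an empty side; supply more pairs")
  }
  ranked <- pairs[order(pairs$ratio, pairs$query_id), ]
  structure(
    list(
      high_substitution = ranked[seq_len(n_side), ],
      low_substitution = ranked[seq(n_total - n_side + 1L, n_total), ],
      n_total = n_total, n_per_side = n_side
    ),
    class = "split_result"
  )
}

#' Classify split genes into functional classes
#'
#' Each selected gene with an annotation E-value strictly below
#' `max_evalue` is assigned to exactly one function — its best (smallest
#' E-value) annotation, ties resolving to the lexicographically smallest
#' function name. Per-function counts of high-substitution ("conserved")
#' and low-substitution ("identical") genes are tallied; genes with no
#' qualifying annotation are counted as unassigned.
#'
#' @param split A [rank_and_split()] result.
#' @param annotation Tibble (`gene_id`, `fun`, `category`, `evalue`).
#' @param max_evalue Annotation E-value ceiling (strict `<`).
#' @return A tibble of class `function_table` (`fun`, `category`,
#'   `conserved_count`, `identical_count`) with an `"unassigned"`
#'   attribute (named counts for the two classes).
#' @export
classify_by_function <- function(split, annotation, max_evalue = 1e-10) {
  stopifnot(inherits(split, "split_result"))
  ann <- annotation[!is.na(annotation$evalue) & annotation$evalue < max_evalue, ]
  ann <- ann[order(ann$gene_id, ann$evalue, ann$fun), ]
  best <- ann[!duplicated(ann$gene_id), c("gene_id", "fun", "category")]
  tally <- function(genes) {
    hit <- best[best$gene_id %in% genes, ]
    list(counts = dplyr::count(hit, .data$fun, .data$category),
         unassigned = length(genes) - nrow(hit))
  }
  cons <- tally(split$high_substitution$query_id)
  iden <- tally(split$low_substitution$query_id)
  tbl <- dplyr::full_join(
    rename(cons$counts, conserved_count = "n"),
    rename(iden$counts, identical_count = "n"),
    by = c("fun", "category")
  )
  tbl <- mutate(tbl, across(
    c("conserved_count", "identical_count"),
    ~ ifelse(is.na(.x), 0L, as.integer(.x))
  ))
  tbl <- arrange(tbl, .data$category, .data$fun)
  attr(tbl, "unassigned") <- c(conserved = cons$unassigned,
                               identical = iden$unassigned)
  class(tbl) <- c("function_table", class(tbl))
  tbl
}

log2_odds_cols <- function(tbl) {
  mutate(
    tbl,
    log2_odds = ifelse(
      .data$conserved_count > 0 & .data$identical_count > 0,
      log2(.data$conserved_count / .data$identical_count),
      ifelse(.data$conserved_count > 0, Inf, -Inf)
    ),
    all_one_class = xor(.data$conserved_count == 0, .data$identical_count == 0)
  )
}

#' Fill the log2 conserved/identical odds column
#'
#' `log2_odds = log2(conserved_count / identical_count)` when both counts
#' are positive. When one count is zero the row is flagged
#' `all_one_class` (the "*" of the published heat plot) and `log2_odds`
#' is the corresponding signed infinity; rows with both counts zero are
#' omitted.
#'
#' @param function_table A [classify_by_function()] result (or any tibble
#'   with `conserved_count` and `identical_count`).
#' @return The table with `log2_odds` and `all_one_class` filled.
#' @export
log2_odds_table <- function(function_table) {
  out <- filter(function_table,
                .data$conserved_count > 0 | .data$identical_count > 0)
  out <- log2_odds_cols(out)
  attr(out, "unassigned") <- attr(function_table, "unassigned")
  if (!inherits(out, "function_table")) {
    class(out) <- c("function_table", class(out))
  }
  out
}

#' Roll functions up to their categories
#'
#' Sums conserved/identical counts over the functions of each category and
#' recomputes log2 odds with the same zero-count handling.
#'
#' @param function_table A table with `fun`, `category` and the two count
#'   columns; every function must map to exactly one non-missing category.
#' @return A per-category tibble with `log2_odds` and `all_one_class`.
#' @export
category_rollup <- function(function_table) {
  if (any(is.na(function_table$category))) {
    bad <- function_table$fun[is.na(function_table$category)]
    abort(paste0("function(s) with unknown category: ",
                 paste(bad, collapse = ", ")))
  }
  out <- summarise(
    group_by(function_table, .data$category),
    conserved_count = sum(.data$conserved_count),
    identical_count = sum(.data$identical_count),
    .groups = "drop"
  )
  out <- filter(out, .data$conserved_count > 0 | .data$identical_count > 0)
  log2_odds_cols(out)
}
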