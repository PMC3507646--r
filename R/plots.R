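# ggplot2 displays for the pipeline's result types.

#' Heat-strip of log2 conserved/identical odds per function
#'
#' Red marks functions dominated by high-substitution ("conserved")
#' proteins, green those dominated by identical proteins; functions whose
#' genes all fall in one class are annotated "*".
#'
#' @param object A function table (with or without `log2_odds` filled).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.function_table <- function(object, ...) {
  t <- tidy.function_table(object)
  fin <- t$log2_odds[is.finite(t$log2_odds)]
  lim <- max(abs(fin), 1)
  t <- mutate(
    t,
    fill_value = pmax(pmin(.data$log2_odds, lim), -lim),
    star = ifelse(.data$all_one_class, "*", "")
  )
  ggplot2::ggplot(t, ggplot2::aes(
    x = 1, y = stats::reorder(.data$fun, .data$fill_value),
    fill = .data$fill_value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star)) +
    ggplot2::scale_fill_gradient2(
      low = "darkgreen", mid = "white", high = "red3",
      limits = c(-lim, lim), name = "log2(conserved/identical)"
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Accumulation-curve plot
#'
#' Mean non-redundant cluster count per subsample size with the
#' replicate range as a ribbon.
#'
#' @param object An [accumulation_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  t <- tidy.accumulation_curve(object)
  ggplot2::ggplot(t, ggplot2::aes(.data$sample_size, .data$mean_clusters)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min_clusters, ymax = .data$max_clusters),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "sequences sampled", y = "non-redundant unigenes") +
    ggplot2::theme_minimal()
}

#' Depth-histogram bar plot
#'
#' @param object A [depth_histogram()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_histogram <- function(object, ...) {
  t <- as_tibble(object)
  t$bin <- factor(t$bin, levels = t$bin)
  ggplot2::ggplot(t, ggplot2::aes(.data$bin, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "unigene depth (reads)", y = "% of unigenes") +
    ggplot2::theme_minimal()
}

#' Histogram of identical match ratios across homolog pairs
#'
#' @param pairs A [build_pairs()] result (or any tibble with `ratio`).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_ratio_distribution <- function(pairs, bins = 30L) {
  ggplot2::ggplot(filter(pairs, !is.na(.data$ratio)),
                  ggplot2::aes(.data$ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "identical match ratio i/(i+h)", y = "pairs") +
    ggplot2::theme_minimal()
}
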