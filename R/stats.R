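# EST-collection summaries: assembly statistics, the doubling-bin depth
# histogram, the unigene accumulation (rarefaction) curve, and annotation
# coverage percentages.

#' Assembly summary statistics by unigene class
#'
#' Unigenes (clusters) of depth >= 2 are contigs; depth-1 unigenes are
#' singletons. Means and medians are computed at full precision; display
#' rounding is left to the caller.
#'
#' @param cluster_sizes Integer vector: reads per unigene.
#' @param lengths Numeric vector: consensus length (bp) per unigene,
#'   aligned with `cluster_sizes`.
#' @return A tibble of class `assembly_stats` with rows `contigs`,
#'   `singletons`, `all` and columns `n`, `total_bases`, `mean_length`,
#'   `median_length`.
#' @export
assembly_stats <- function(cluster_sizes, lengths) {
  if (!length(cluster_sizes)) abort("empty input")
  stopifnot(length(cluster_sizes) == length(lengths), all(cluster_sizes >= 1))
  one <- function(class, len) {
    tibble(class = class, n = length(len), total_bases = sum(len),
           mean_length = mean(len), median_length = median(len))
  }
  contig <- cluster_sizes >= 2
  out <- bind_rows(
    one("contigs", lengths[contig]),
    one("singletons", lengths[!contig]),
    one("all", lengths)
  )
  class(out) <- c("assembly_stats", class(out))
  out
}

depth_bin_label <- function(k) {
  ifelse(k == 0, "1",
         ifelse(k == 1, "2", paste0(2^(k - 1) + 1, "-", 2^k)))
}

#' Doubling-bin histogram of unigene depths
#'
#' Bin 0 holds depth-1 unigenes (singletons); bin k >= 1 covers depths in
#' `(2^(k-1), 2^k]` — the printed 1 / 2 / 3-4 / 5-8 / ... scheme. The bins
#' partition the positive integers. Percentages are over the total
#' unigene count and accumulate to 100.
#'
#' @param cluster_sizes Integer vector of depths (>= 1).
#' @return A tibble of class `depth_histogram` (`bin`, `depth_min`,
#'   `depth_max`, `count`, `percent`, `cumulative_percent`).
#' @export
depth_histogram <- function(cluster_sizes) {
  if (any(cluster_sizes < 1)) abort("cluster sizes must be >= 1")
  k <- ifelse(cluster_sizes == 1, 0L, ceiling(log2(cluster_sizes)))
  kmax <- max(k)
  counts <- vapply(0:kmax, function(b) sum(k == b), 0L)
  out <- tibble(
    bin = depth_bin_label(0:kmax),
    depth_min = c(1L, 2L, 2^(seq_len(kmax)[-1] - 1) + 1L)[seq_len(kmax + 1)],
    depth_max = c(1L, 2^seq_len(kmax)),
    count = counts,
    percent = 100 * counts / length(cluster_sizes)
  )
  out$cumulative_percent <- cumsum(out$percent)
  class(out) <- c("depth_histogram", class(out))
  out
}

#' Cluster-count function from planted truth
#'
#' Returns a clusterer that looks sampled ESTs up in the generator's truth
#' table — the identity clusterer for rarefaction tests.
#'
#' @param truth Tibble (`est_id`, `cluster`).
#' @return A function mapping a sequence tibble to its distinct-cluster
#'   count.
#' @export
truth_clusterer <- function(truth) {
  map <- setNames(truth$cluster, truth$est_id)
  function(sequences) dplyr::n_distinct(map[sequences$id])
}

#' Greedy single-linkage identity clusterer
#'
#' Clusters sequences whose pairwise identity (edit distance over the
#' longer length) reaches `min_identity` with mutual length overlap of at
#' least `min_overlap` — an explicit desk-scale stand-in for assembly
#' software, injectable into [accumulation_curve()].
#'
#' @param min_identity Identity threshold in \[0, 1\].
#' @param min_overlap Minimum shorter/longer length ratio.
#' @return A function mapping a sequence tibble to a cluster count.
#' @export
greedy_identity_clusterer <- function(min_identity = 0.95, min_overlap = 0.8) {
  function(sequences) {
    n <- nrow(sequences)
    if (n <= 1) return(n)
    len <- nchar(sequences$seq)
    d <- adist(sequences$seq)
    longer <- outer(len, len, pmax)
    shorter <- outer(len, len, pmin)
    link <- (1 - d / longer) >= min_identity & shorter / longer >= min_overlap
    g <- igraph::graph_from_adjacency_matrix(link, mode = "undirected")
    igraph::components(g)$no
  }
}

#' Unigene accumulation (rarefaction) curve
#'
#' Each replicate draws one random permutation of the collection; for
#' every subsample size in `sizes_grid` the permutation's prefix of that
#' size is clustered and the non-redundant cluster count recorded. A
#' prefix of a random permutation is a uniform without-replacement sample,
#' and nesting makes each replicate's curve non-decreasing under a
#' consistent clusterer. Sub-seeds per replicate derive from `seed`.
#'
#' @param sequences Sequence tibble (`id`, `seq`).
#' @param sizes_grid Integer vector of subsample sizes; defaults to 20
#'   evenly spaced sizes up to the collection size. Sizes beyond the
#'   collection are an error.
#' @param replicates Draws per size.
#' @param clusterer Function from a sequence tibble to a cluster count,
#'   e.g. [truth_clusterer()] or [greedy_identity_clusterer()].
#' @param seed Integer seed governing all draws.
#' @return A tibble of class `accumulation_curve` (`sample_size`,
#'   `replicate`, `clusters`) with the seed attached as attribute.
#' @export
accumulation_curve <- function(sequences, sizes_grid = NULL, replicates = 20L,
                               clusterer = greedy_identity_clusterer(),
                               seed = 1L) {
  n <- nrow(sequences)
  if (is.null(sizes_grid)) {
    sizes_grid <- unique(pmax(1L, round(seq_len(20L) * n / 20)))
  }
  if (any(sizes_grid > n)) abort("grid size exceeds collection size")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  out <- purrr::map_dfr(seq_len(replicates), function(r) {
    set.seed(sub_seeds[r])
    perm <- sample.int(n, n)
    purrr::map_dfr(sizes_grid, function(s) {
      tibble(sample_size = s, replicate = r,
             clusters = clusterer(sequences[perm[seq_len(s)], ]))
    })
  })
  attr(out, "seed") <- seed
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Annotation coverage percentage
#'
#' @param annotated_count,total_count Non-negative counts with
#'   `annotated_count <= total_count` and `total_count > 0`.
#' @return `100 * annotated_count / total_count` (full precision; the
#'   conventional display rounds to one decimal).
#' @examples
#' round(annotation_coverage(7334, 13167), 1) # 55.7
#' @export
annotation_coverage <- function(annotated_count, total_count) {
  if (total_count <= 0) abort("total_count must be positive")
  if (annotated_count < 0 || annotated_count > total_count) {
    abort("annotated_count must lie in [0, total_count]")
  }
  100 * annotated_count / total_count
}
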