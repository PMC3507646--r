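# Independent oracles used across the suite. These stay deliberately
# naive: enumeration, closed forms and brute-force closure, never the
# package's own code paths.

# best local alignment score by exhaustive enumeration: every substring
# pair, every monotone column path, affine gaps costing open + k * extend
sw_enumerate <- function(pepA, pepB, mat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(pepA, "")[[1]]
  b <- strsplit(pepB, "")[[1]]
  align_rest <- function(ai, bi, a2, b2, last) {
    if (ai > a2 && bi > b2) return(0)
    best <- -Inf
    if (ai <= a2 && bi <= b2) {
      best <- max(best, mat[a[ai], b[bi]] + align_rest(ai + 1, bi + 1, a2, b2, "M"))
    }
    if (ai <= a2) {
      cost <- if (identical(last, "D")) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + align_rest(ai + 1, bi, a2, b2, "D"))
    }
    if (bi <= b2) {
      cost <- if (identical(last, "I")) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + align_rest(ai, bi + 1, a2, b2, "I"))
    }
    best
  }
  best <- 0
  for (i1 in seq_along(a)) for (i2 in i1:length(a)) {
    for (j1 in seq_along(b)) for (j2 in j1:length(b)) {
      best <- max(best, align_rest(i1, j1, i2, j2, "start"))
    }
  }
  best
}

# transitive closure by boolean matrix powers: which terms are reachable
# from which roots
reachability_oracle <- function(edges, roots) {
  terms <- unique(c(edges$parent, edges$child, roots))
  n <- length(terms)
  adj <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  adj[cbind(edges$parent, edges$child)] <- TRUE
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  out <- list()
  for (r in roots) {
    out[[r]] <- terms[reach[r, ]]
  }
  out
}

# expected number of distinct clusters when sampling n of N sequences
# without replacement (hypergeometric coverage)
expected_accumulation <- function(cluster_sizes, n) {
  N <- sum(cluster_sizes)
  sum(1 - exp(lchoose(N - cluster_sizes, n) - lchoose(N, n)))
}

# variance of the distinct-cluster count under the same sampling model
var_accumulation <- function(cluster_sizes, n) {
  N <- sum(cluster_sizes)
  p_absent <- function(s) exp(lchoose(N - s, n) - lchoose(N, n))
  p_both_absent <- function(s1, s2) exp(lchoose(N - s1 - s2, n) - lchoose(N, n))
  m <- length(cluster_sizes)
  v <- sum(vapply(cluster_sizes, function(s) p_absent(s) * (1 - p_absent(s)), 0))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) {
      v <- v + p_both_absent(cluster_sizes[i], cluster_sizes[j]) -
        p_absent(cluster_sizes[i]) * p_absent(cluster_sizes[j])
    }
  }
  v
}

random_peptide <- function(n, alphabet = c("A", "R", "N", "D")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dag_edges <- function(n_terms, p_edge = 0.25) {
  terms <- sprintf("t%02d", seq_len(n_terms))
  from <- c(); to <- c()
  for (i in seq_len(n_terms - 1)) for (j in seq(i + 1, n_terms)) {
    if (runif(1) < p_edge) {
      from <- c(from, terms[i]); to <- c(to, terms[j])
    }
  }
  tibble::tibble(parent = from, child = to)
}
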