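test_that("assembly statistics partition unigenes into contigs and singletons", {
  sizes <- c(3, 1, 2, 1, 1, 5)
  lens <- c(1200, 500, 900, 450, 600, 2000)
  st <- assembly_stats(sizes, lens)
  get <- function(cl) st[st$class == cl, ]
  expect_equal(get("contigs")$n, 3L)
  expect_equal(get("singletons")$n, 3L)
  expect_equal(get("all")$n, get("contigs")$n + get("singletons")$n)
  expect_equal(get("all")$total_bases,
               get("contigs")$total_bases + get("singletons")$total_bases)
  expect_equal(get("contigs")$mean_length, mean(c(1200, 900, 2000)))
  one <- assembly_stats(1, 750)
  expect_equal(one[one$class == "all", ]$mean_length, 750)
  expect_equal(one[one$class == "all", ]$median_length, 750)
  expect_error(assembly_stats(numeric(), numeric()), "empty")
})

test_that("the published contig-class arithmetic holds in the fixture", {
  summ <- load_assembly_summary()
  contig <- summ[summ$class == "contigs", ]
  expect_equal(round(contig$mean_length, 1), 1360.4)
  expect_equal(summ$n[summ$class == "all"],
               sum(summ$n[summ$class != "all"])) # 4883 + 8284 = 13167
  expect_equal(summ$total_bases[summ$class == "all"],
               sum(summ$total_bases[summ$class != "all"]))
})

test_that("depth histogram bins follow the doubling scheme", {
  h <- depth_histogram(c(1, 1, 2, 3, 5, 9))
  expect_equal(h$bin, c("1", "2", "3-4", "5-8", "9-16"))
  expect_equal(h$count, c(2L, 1L, 1L, 1L, 1L))
  expect_equal(sum(h$percent), 100)
  expect_equal(tail(h$cumulative_percent, 1), 100)
  expect_true(all(diff(h$cumulative_percent) >= 0))
  expect_error(depth_histogram(c(1, 0)), ">= 1")
})

test_that("doubling bins partition the positive integers", {
  h <- depth_histogram(c(1, 2^20)) # widest span we care about
  edges <- tibble::tibble(lo = h$depth_min, hi = h$depth_max)
  expect_equal(edges$lo[1], 1L)
  expect_equal(edges$lo[-1], head(edges$hi, -1) + 1L)
  # spot-check membership for sizes up to 1e6
  sizes <- c(1:64, sort(sample.int(1e6, 200)))
  k <- ifelse(sizes == 1, 0, ceiling(log2(sizes)))
  lo <- ifelse(k == 0, 1, 2^(k - 1) + 1)
  hi <- ifelse(k == 0, 1, 2^k)
  expect_true(all(sizes >= lo & sizes <= hi))
})

test_that("percentages normalise for random size vectors", {
  set.seed(33)
  for (k in 1:5) {
    sizes <- sample.int(50, 200, TRUE)
    h <- depth_histogram(sizes)
    expect_equal(sum(h$count), 200L)
    expect_equal(sum(h$percent), 100)
  }
})

test_that("a simulated EST collection reproduces its planted depth profile", {
  sizes <- c(16, 8, 8, 4, 2, 1, 1, 1)
  est <- simulate_est_collection(8, sizes, seed = 21)
  observed <- as.integer(table(est$truth$cluster))
  expect_equal(depth_histogram(observed)$count, depth_histogram(sizes)$count)
})

test_that("accumulation equals sample size when every cluster is a singleton", {
  est <- simulate_est_collection(10, rep(1, 10), seed = 8)
  curve <- accumulation_curve(est$sequences, sizes_grid = c(2, 5, 10),
                              replicates = 3,
                              clusterer = truth_clusterer(est$truth), seed = 9)
  expect_equal(curve$clusters, curve$sample_size)
})

test_that("the full-collection sample recovers the true cluster count", {
  sizes <- c(5, 3, 2, 1, 1)
  est <- simulate_est_collection(5, sizes, seed = 10)
  n <- nrow(est$sequences)
  curve <- accumulation_curve(est$sequences, sizes_grid = n, replicates = 2,
                              clusterer = truth_clusterer(est$truth), seed = 3)
  expect_true(all(curve$clusters == 5))
  expect_error(
    accumulation_curve(est$sequences, sizes_grid = n + 1, replicates = 1,
                       clusterer = truth_clusterer(est$truth)),
    "exceeds"
  )
})

test_that("curves are deterministic in the seed and monotone on average", {
  est <- simulate_est_collection(12, c(8, 6, 5, 4, 3, 3, 2, 2, 1, 1, 1, 1),
                                 seed = 40)
  c1 <- accumulation_curve(est$sequences, replicates = 5,
                           clusterer = truth_clusterer(est$truth), seed = 2)
  c2 <- accumulation_curve(est$sequences, replicates = 5,
                           clusterer = truth_clusterer(est$truth), seed = 2)
  expect_identical(c1, c2)
  t <- generics::tidy(c1)
  expect_true(all(diff(t$mean_clusters) >= 0))
  expect_true(all(t$mean_clusters <= 12))
})

test_that("the greedy identity clusterer groups near-identical copies", {
  est <- simulate_est_collection(4, c(3, 2, 2, 1), seed = 55,
                                 exemplar_len_nt = 200,
                                 mutation_rate = 0.01)
  n_found <- greedy_identity_clusterer()(est$sequences)
  expect_equal(n_found, 4)
})

test_that("annotation coverage matches the printed percentages", {
  expect_equal(round(annotation_coverage(7334, 13167), 1), 55.7)
  expect_equal(round(annotation_coverage(843, 952), 1), 88.6)
  expect_equal(annotation_coverage(0, 10), 0)
  expect_error(annotation_coverage(1, 0), "positive")
  expect_error(annotation_coverage(11, 10), "\\[0, total_count\\]")
})

test_that("the EST library fixture sums to the printed totals", {
  lib <- load_est_library_table()
  expect_equal(sum(lib$reads_5p), 43060L)
  expect_equal(sum(lib$reads_3p), 18461L)
  expect_equal(sum(lib$overlap_contigs), 11093L)
  expect_equal(sum(lib$full_inserts), 593L)
})
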