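test_that("spectrum validation enforces the probability simplex", {
  expect_error(substitution_spectrum(0.5, 0.4, 0.2), "sum to 1")
  expect_error(substitution_spectrum(1.1, -0.1, 0), "non-negative")
  expect_error(substitution_spectrum(1, 0, 0, length_codons = 10), "at least 30")
  sp <- substitution_spectrum(0.6, 0.2, 0.2)
  expect_equal(sp$expected_ratio, 0.75)
})

test_that("a pure-identity spectrum yields identical translated sequences", {
  sp <- substitution_spectrum(1, 0, 0, length_codons = 40)
  pair <- simulate_homolog_pair(sp, seed = 11)
  expect_equal(pair$expected_ratio, 1)
  tq <- six_frame_translate(pair$query$seq)$peptide[1]
  ts <- six_frame_translate(pair$subject$seq)$peptide[1]
  expect_equal(tq, ts)
  expect_false(grepl("*", tq, fixed = TRUE)) # no internal stops
})

test_that("site logs classify every substitution consistently with BLOSUM62", {
  m <- blosum62()
  sp <- substitution_spectrum(0.6, 0.2, 0.2, length_codons = 120)
  for (seed in 1:10) {
    log <- simulate_homolog_pair(sp, seed = seed)$site_log
    cons <- log[log$class == "conservative", ]
    rad <- log[log$class == "radical", ]
    iden <- log[log$class == "identical", ]
    expect_true(all(m[cbind(cons$anc_aa, cons$der_aa)] > 0))
    expect_true(all(cons$anc_aa != cons$der_aa))
    expect_true(all(m[cbind(rad$anc_aa, rad$der_aa)] <= 0))
    expect_identical(iden$anc_aa, iden$der_aa)
  }
})

test_that("observed ratio on the true alignment recovers the planted value", {
  sp <- substitution_spectrum(0.5, 0.5, 0, length_codons = 300)
  pair <- simulate_homolog_pair(sp, seed = 202)
  tq <- six_frame_translate(pair$query$seq)$peptide[1]
  ts <- six_frame_translate(pair$subject$seq)$peptide[1]
  prof <- classify_columns(tq, ts)
  se <- sqrt(0.5 * 0.5 / 300)
  expect_lt(abs(identical_match_ratio(prof) - 0.5), 3 * se)
  # the site log is a sufficient statistic: same counts without re-alignment
  log <- pair$site_log
  expect_equal(prof$i, sum(log$class == "identical"))
  expect_equal(prof$h, sum(log$class == "conservative"))
})

test_that("generators are deterministic given the seed", {
  sp <- substitution_spectrum(0.7, 0.2, 0.1, length_codons = 50)
  expect_identical(simulate_homolog_pair(sp, seed = 5),
                   simulate_homolog_pair(sp, seed = 5))
  est1 <- simulate_est_collection(5, c(1, 2, 3, 4, 5), seed = 9)
  est2 <- simulate_est_collection(5, c(1, 2, 3, 4, 5), seed = 9)
  expect_identical(est1, est2)
})

test_that("codon indels keep both sequences in frame", {
  sp <- substitution_spectrum(0.8, 0.1, 0.1, indel_rate = 0.05,
                              length_codons = 100)
  pair <- simulate_homolog_pair(sp, seed = 31)
  expect_equal(nchar(pair$query$seq) %% 3, 0)
  expect_equal(nchar(pair$subject$seq) %% 3, 0)
  expect_false(grepl("*", six_frame_translate(pair$subject$seq)$peptide[1],
                     fixed = TRUE))
})

test_that("function panels plant distinguishable substitution regimes", {
  spectra <- list(
    flexible = substitution_spectrum(0.70, 0.30, 0, length_codons = 60),
    rigid = substitution_spectrum(0.98, 0.02, 0, length_codons = 60)
  )
  panel <- simulate_function_panel(10, spectra, seed = 77)
  expect_equal(nrow(panel$query_set), 20L)
  expect_equal(sort(unique(panel$truth$fun)), c("flexible", "rigid"))
  ratios <- tapply(panel$truth$expected_ratio, panel$truth$fun, unique)
  expect_lt(ratios[["flexible"]], ratios[["rigid"]])
  expect_error(simulate_function_panel(10, spectra[1], seed = 1),
               "at least 2 functions")
})

test_that("target datasets honour the presence plan", {
  genes <- simulate_function_panel(
    4, list(a = substitution_spectrum(0.9, 0.1, 0, length_codons = 60),
            b = substitution_spectrum(0.9, 0.1, 0, length_codons = 60)),
    seed = 3
  )$query_set
  plan <- tidyr::expand_grid(gene_id = genes$id, dataset = c("dsA", "dsB"))
  plan$present <- plan$dataset == "dsA" | seq_len(nrow(plan)) %% 2 == 0
  sim <- simulate_target_datasets(genes, plan, decoy_count = 2, seed = 4)
  expect_named(sim$datasets, c("dsA", "dsB"))
  expect_equal(nrow(sim$datasets$dsA),
               sum(plan$present[plan$dataset == "dsA"]) + 2)
  expect_error(
    simulate_target_datasets(genes, dplyr::mutate(plan, gene_id = "nope"),
                             seed = 1),
    "unknown gene"
  )
  # empty dataset accepted
  empty_plan <- tibble::tibble(gene_id = genes$id[1], dataset = "dsC",
                               present = FALSE)
  sim0 <- simulate_target_datasets(genes, empty_plan, decoy_count = 0, seed = 5)
  expect_equal(nrow(sim0$datasets$dsC), 0L)
})

test_that("genome-like targets still yield a present call via local segments", {
  genes <- tibble::tibble(
    id = "gene1",
    seq = simulate_homolog_pair(
      substitution_spectrum(1, 0, 0, length_codons = 80), seed = 6
    )$query$seq
  )
  plan <- tibble::tibble(gene_id = "gene1", dataset = "genome", present = TRUE)
  sim <- simulate_target_datasets(genes, plan, seed = 7,
                                  genome_like = "genome")
  target <- sim$datasets$genome
  expect_gt(nchar(target$seq[1]), nchar(genes$seq[1])) # spacer inserted
  hit <- best_translated_hit(as.list(genes[1, ]), as.list(target[1, ]))
  expect_false(is.null(hit))
  expect_lt(hit$evalue, 1e-10)
})

test_that("EST collections record the cluster of every read", {
  sizes <- c(8, 4, 2, 1, 1)
  est <- simulate_est_collection(5, sizes, seed = 12, mutation_rate = 0.01)
  expect_equal(nrow(est$sequences), sum(sizes))
  expect_equal(as.integer(table(est$truth$cluster)), sizes)
  # near-identical copies: every EST within 1% of its exemplar length in edits
  first_of <- est$sequences$seq[!duplicated(est$truth$cluster)]
  d <- utils::adist(est$sequences$seq[1], est$sequences$seq[2])
  expect_lt(d / nchar(est$sequences$seq[1]), 0.025)
})
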