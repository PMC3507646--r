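test_that("columns classify by published matrix constants", {
  p <- classify_columns("A", "A")
  expect_equal(c(p$i, p$h, p$m, p$g), c(1, 0, 0, 0))
  p <- classify_columns("K", "R") # BLOSUM62(K,R) = +2
  expect_equal(c(p$i, p$h, p$m, p$g), c(0, 1, 0, 0))
  p <- classify_columns("L", "D") # BLOSUM62(L,D) = -4
  expect_equal(c(p$i, p$h, p$m, p$g), c(0, 0, 1, 0))
  p <- classify_columns("AC-D", "ACED")
  expect_equal(c(p$i, p$h, p$m, p$g), c(3, 0, 0, 1))
  expect_equal(p$region_len_nt, 9)
  expect_error(classify_columns("AC", "ACD"), "equal length")
  expect_error(classify_columns("A-C", "A-C"), "both rows")
})

test_that("X and stop columns are never identical nor homologous", {
  p <- classify_columns("XWX*", "XWW*")
  # X/X, W/W, X/W, */*: only W/W is identical; X and * columns are m
  expect_equal(c(p$i, p$h, p$m, p$g), c(1, 0, 3, 0))
})

test_that("classification is exhaustive and symmetric for random alignments", {
  set.seed(88)
  alpha <- c(rownames(blosum62())[1:20], "X")
  for (k in 1:25) {
    n <- sample(5:40, 1)
    a <- sample(alpha, n, TRUE)
    b <- sample(alpha, n, TRUE)
    gap <- runif(n) < 0.15
    a[gap & runif(n) < 0.5] <- "-"
    b[gap & a != "-"] <- ifelse(runif(sum(gap & a != "-")) < 0.5, "-",
                                b[gap & a != "-"])
    pa <- paste(a, collapse = ""); pb <- paste(b, collapse = "")
    p <- classify_columns(pa, pb)
    expect_equal(p$i + p$h + p$m + p$g, n)
    q <- classify_columns(pb, pa)
    expect_equal(p[c("i", "h", "m", "g")], q[c("i", "h", "m", "g")])
  }
})

test_that("the identical match ratio behaves as i/(i+h)", {
  mk <- function(i, h, m = 0, g = 0) {
    structure(list(i = i, h = h, m = m, g = g,
                   region_len_nt = 3 * (i + h + m)),
              class = "match_profile")
  }
  expect_equal(identical_match_ratio(mk(10, 0)), 1)
  expect_equal(identical_match_ratio(mk(0, 5)), 0)
  r <- identical_match_ratio(mk(18, 5))
  expect_equal(r, 18 / 23)
  expect_equal(round(r, 2), 0.78) # two-decimal display convention
  expect_error(identical_match_ratio(mk(0, 0)), "undefined")
  # strictly decreasing in h with i fixed
  rs <- vapply(0:10, function(h) identical_match_ratio(mk(6, h)), 0)
  expect_true(all(diff(rs) < 0))
  expect_true(all(rs >= 0 & rs <= 1))
})

test_that("the filter cascade keeps boundary values and reports attrition", {
  cfg <- run_config()
  pairs <- tibble::tibble(
    query_id = sprintf("q%d", 1:5),
    query_len_nt = c(599, 600, 900, 900, 900),
    evalue = c(1e-40, 1e-30, 1e-29, 1e-40, 1e-40),
    region_nt = c(100, 80, 100, 79, 80)
  )
  out <- filter_pairs(pairs, cfg)
  expect_equal(out$passed, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$fail_reasons[c(1, 3, 4)],
               c("query_length", "evalue", "region"))
  att <- attr(out, "attrition")
  expect_equal(att$removed, c(1, 1, 1))
  # independent re-scan of the conjunction
  manual <- pairs$query_len_nt >= 600 & pairs$evalue <= 1e-30 &
    pairs$region_nt >= 80
  expect_equal(out$passed, manual)
})

test_that("attrition counts follow application order on random panels", {
  set.seed(91)
  pairs <- tibble::tibble(
    query_id = sprintf("q%03d", 1:200),
    query_len_nt = sample(c(400, 700), 200, TRUE),
    evalue = 10^-sample(c(20, 40), 200, TRUE),
    region_nt = sample(c(60, 120), 200, TRUE)
  )
  out <- filter_pairs(pairs, run_config())
  att <- attr(out, "attrition")
  expect_equal(sum(att$removed), sum(!out$passed))
  expect_equal(att$removed[1], sum(pairs$query_len_nt < 600))
})

test_that("pair building finds each query's true homolog among decoys", {
  sp <- substitution_spectrum(0.85, 0.1, 0.05, length_codons = 60)
  set.seed(14)
  pairs <- lapply(1:6, function(k) simulate_homolog_pair(sp, seed = 1000 + k,
                                                         id = paste0("p", k)))
  query_set <- purrr::map_dfr(pairs, function(p) tibble::as_tibble(p$query))
  subject_set <- purrr::map_dfr(pairs, function(p) tibble::as_tibble(p$subject))
  cfg <- run_config(min_query_len_nt = 60, max_evalue_pair = 1e-10,
                    min_region_nt = 60)
  built <- build_pairs(query_set, subject_set, config = cfg)
  expect_equal(nrow(built), 6L)
  expect_equal(built$subject_id, sub("_q$", "_s", built$query_id))
  expect_true(all(built$passed))
  expect_true(all(built$i + built$h + built$m + built$g > 0))
})

test_that("all-decoy subject sets yield zero pairs at strict thresholds", {
  set.seed(15)
  q <- tibble::tibble(id = "q1", seq = paste(
    sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""
  ))
  s <- tibble::tibble(id = sprintf("d%d", 1:4), seq = vapply(1:4, function(k) {
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  }, ""))
  built <- build_pairs(q, s, config = run_config())
  expect_true(nrow(built) == 0 || !any(built$passed))
})

test_that("mean observed ratio tracks the planted expectation over seeds", {
  sp <- substitution_spectrum(0.7, 0.3, 0, length_codons = 200)
  ratios <- vapply(1:30, function(seed) {
    pair <- simulate_homolog_pair(sp, seed = 4000 + seed)
    tq <- six_frame_translate(pair$query$seq)$peptide[1]
    ts <- six_frame_translate(pair$subject$seq)$peptide[1]
    identical_match_ratio(classify_columns(tq, ts))
  }, 0)
  se <- sqrt(0.7 * 0.3 / (200 * 30))
  expect_lt(abs(mean(ratios) - 0.7), 3 * se)
})
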