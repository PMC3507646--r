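# The core statistic: alignment-column classification, the identical match
# ratio i/(i+h), and the homolog-pair filter cascade.

#' Classify the columns of a peptide alignment
#'
#' Each column of the aligned pair is classified as an identical match
#' (`i`, same standard residue on both rows), a homologous substitution
#' (`h`, distinct residues with a positive substitution-matrix score — the
#' "+" of a search-tool midline), a non-similar mismatch (`m`, score <= 0,
#' or any `X`/stop symbol), or a gap column (`g`). Columns that are gaps in
#' both rows are invalid. The conserved-region span is `3 * (i + h + m)`
#' nucleotides: gap columns are excluded from the span accounting.
#'
#' @param aligned_query,aligned_subject Equal-length aligned strings with
#'   `-` gap characters.
#' @param scheme A [scoring_scheme()].
#' @return A list of class `match_profile` with counts `i`, `h`, `m`, `g`
#'   and `region_len_nt`.
#' @examples
#' classify_columns("ACKD", "ACRD") # K/R scores +2: i = 3, h = 1
#' @export
classify_columns <- function(aligned_query, aligned_subject,
                             scheme = scoring_scheme()) {
  if (nchar(aligned_query) != nchar(aligned_subject)) {
    abort("aligned strings must have equal length")
  }
  a <- strsplit(aligned_query, "")[[1]]
  b <- strsplit(aligned_subject, "")[[1]]
  if (any(a == "-" & b == "-")) abort("column with gaps in both rows")
  gap <- a == "-" | b == "-"
  std <- a %in% STANDARD_AA & b %in% STANDARD_AA
  ident <- !gap & std & a == b
  score <- rep(NA_real_, length(a))
  res <- !gap & std & a != b
  if (any(res)) score[res] <- scheme$matrix[cbind(a[res], b[res])]
  homol <- res & !is.na(score) & score > 0
  i <- sum(ident); h <- sum(homol); g <- sum(gap)
  m <- length(a) - i - h - g
  structure(
    list(i = i, h = h, m = m, g = g, region_len_nt = 3L * (i + h + m)),
    class = "match_profile"
  )
}

#' The identical match ratio
#'
#' The number of identical matches divided by the sum of identical matches
#' plus homologous substitutions, `i / (i + h)`. Low values indicate high
#' flexibility of amino-acid substitutions in the conserved region.
#' Undefined (an error) when `i + h = 0`; such pairs are excluded upstream.
#'
#' @param profile A `match_profile` from [classify_columns()].
#' @return A number in \[0, 1\].
#' @export
identical_match_ratio <- function(profile) {
  if (profile$i + profile$h == 0) {
    abort("ratio undefined: alignment has no identical or homologous columns")
  }
  profile$i / (profile$i + profile$h)
}

#' Apply the homolog-pair filter cascade
#'
#' A pair is retained iff the query unigene is at least
#' `min_query_len_nt` long AND the pair E-value is at most
#' `max_evalue_pair` AND the conserved region spans at least
#' `min_region_nt` nucleotides (boundary values retained). Filters are
#' applied in that order and the attrition report counts removals per
#' criterion in application order.
#'
#' @param pairs A tibble with columns `query_len_nt`, `evalue`,
#'   `region_nt` (as produced by [build_pairs()]).
#' @param config A [run_config()].
#' @return `pairs` with `passed` (logical) and `fail_reasons` (character)
#'   filled, and the attrition tibble attached as attribute `"attrition"`.
#' @export
filter_pairs <- function(pairs, config = run_config()) {
  fail_len <- pairs$query_len_nt < config$min_query_len_nt
  fail_ev <- pairs$evalue > config$max_evalue_pair
  fail_reg <- pairs$region_nt < config$min_region_nt
  pairs$passed <- !(fail_len | fail_ev | fail_reg)
  reasons <- purrr::pmap_chr(
    list(fail_len, fail_ev, fail_reg),
    function(l, e, r) {
      paste(c(
        if (l) "query_length", if (e) "evalue", if (r) "region"
      ), collapse = ";")
    }
  )
  pairs$fail_reasons <- reasons
  attrition <- tibble(
    criterion = c("query_length", "evalue", "region"),
    removed = c(
      sum(fail_len),
      sum(!fail_len & fail_ev),
      sum(!fail_len & !fail_ev & fail_reg)
    )
  )
  attr(pairs, "attrition") <- attrition
  pairs
}

#' Build homolog pairs between two unigene sets
#'
#' For each query, the best translated hit against every subject is
#' computed and the best subject retained (by raw score; ties resolve to
#' the lexicographically smallest subject id). Column classification, the
#' identical match ratio and the filter cascade are then applied. Queries
#' with no positive-scoring hit are dropped.
#'
#' @param query_set,subject_set Sequence tibbles (`id`, `seq`).
#' @param scheme A [scoring_scheme()].
#' @param config A [run_config()].
#' @param pairing `"all"` searches every subject per query; `"matched"`
#'   pairs the i-th query with the i-th subject (for pre-matched panels).
#' @param min_segment_aa Passed to [best_translated_hit()].
#' @return A tibble of class `homolog_pairs` with one row per paired
#'   query: ids, frames, score, E-value, `i`, `h`, `m`, `g`, `region_nt`,
#'   `query_len_nt`, `ratio`, `passed`, `fail_reasons`; attrition attached
#'   as for [filter_pairs()].
#' @export
build_pairs <- function(query_set, subject_set, scheme = scoring_scheme(),
                        config = run_config(), pairing = c("all", "matched"),
                        min_segment_aa = 8L) {
  pairing <- match.arg(pairing)
  if (!nrow(query_set) || !nrow(subject_set)) {
    abort("both sequence sets must be non-empty")
  }
  rows <- purrr::map_dfr(seq_len(nrow(query_set)), function(qi) {
    query <- as.list(query_set[qi, ])
    cand <- if (pairing == "matched") subject_set[qi, ] else subject_set
    cand <- cand[order(cand$id), ]
    best <- NULL
    for (sj in seq_len(nrow(cand))) {
      hit <- best_translated_hit(query, as.list(cand[sj, ]), scheme,
                                 min_segment_aa = min_segment_aa)
      if (!is.null(hit) &&
          (is.null(best) || hit$raw_score > best$raw_score)) {
        best <- hit
      }
    }
    if (is.null(best)) return(NULL)
    prof <- classify_columns(best$aligned_query, best$aligned_subject, scheme)
    tibble(
      query_id = query$id, subject_id = best$subject_id,
      query_frame = best$query_frame, subject_frame = best$subject_frame,
      score = best$raw_score, evalue = best$evalue,
      i = prof$i, h = prof$h, m = prof$m, g = prof$g,
      region_nt = prof$region_len_nt,
      query_len_nt = nchar(query$seq),
      ratio = if (prof$i + prof$h > 0) identical_match_ratio(prof) else NA_real_
    )
  })
  out <- filter_pairs(rows, config)
  class(out) <- c("homolog_pairs", class(out))
  out
}
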