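# Translated local alignment: Smith-Waterman (affine gaps) over peptide
# segments from all 36 reading-frame pairs, standing in for TBLASTX-style
# searches at desk scale.

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman with affine gaps under the scheme's substitution matrix
#' and penalties (delegated to `Biostrings::pairwiseAlignment`). When no
#' positive-scoring alignment exists the empty alignment with score 0 is
#' returned.
#'
#' @param pepA,pepB Non-empty peptide strings (no stop symbols).
#' @param scheme A [scoring_scheme()].
#' @return A list with `score`, `aligned_query`, `aligned_subject`, and the
#'   1-based residue spans `query_span_aa`, `subject_span_aa` (NA for the
#'   empty alignment).
#' @export
local_align <- function(pepA, pepB, scheme = scoring_scheme()) {
  if (!nzchar(pepA) || !nzchar(pepB)) abort("peptides must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(pepA), Biostrings::AAStringSet(pepB),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(
      score = 0, aligned_query = "", aligned_subject = "",
      query_span_aa = c(NA_integer_, NA_integer_),
      subject_span_aa = c(NA_integer_, NA_integer_)
    ))
  }
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  list(
    score = sc,
    aligned_query = as.character(pat),
    aligned_subject = as.character(sub),
    query_span_aa = c(Biostrings::start(pat), Biostrings::end(pat)),
    subject_span_aa = c(Biostrings::start(sub), Biostrings::end(sub))
  )
}

# split a frame translation at stop codons into alignable segments;
# offset is the 0-based residue offset of each segment within the frame
peptide_segments <- function(peptide, min_len = 1L) {
  if (!nzchar(peptide)) {
    return(list(segment = character(), offset = integer()))
  }
  parts <- strsplit(peptide, "*", fixed = TRUE)[[1]]
  offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) >= min_len
  list(segment = parts[keep], offset = offs[keep])
}

frame_segments <- function(seq, min_len) {
  tr <- six_frame_translate(seq)
  segment <- character()
  offset <- integer()
  frame <- integer()
  for (k in seq_along(tr$frame)) {
    segs <- peptide_segments(tr$peptide[k], min_len)
    segment <- c(segment, segs$segment)
    offset <- c(offset, segs$offset)
    frame <- c(frame, rep(tr$frame[k], length(segs$segment)))
  }
  list(segment = segment, offset = offset, frame = frame)
}

# map a 1-based residue span within a frame translation back to 1-based
# inclusive nucleotide coordinates on the original strand
aa_span_to_nt <- function(frame, offset, aa_start, aa_end, seq_len) {
  f <- abs(frame)
  a1 <- offset + aa_start
  a2 <- offset + aa_end
  s <- (f - 1L) + 3L * (a1 - 1L) + 1L
  e <- (f - 1L) + 3L * a2
  if (frame > 0) c(s, e) else c(seq_len - e + 1L, seq_len - s + 1L)
}

#' Best translated hit between two nucleotide sequences
#'
#' Translates both sequences in all six frames, splits each frame at stop
#' codons (stops terminate candidate segments; they are never scored), and
#' returns the best-scoring local alignment over all frame-pair segment
#' combinations, or `NULL` when nothing scores above zero or the best
#' E-value exceeds `max_evalue`. Ties resolve to the earliest frame pair in
#' the order +1, +2, +3, -1, -2, -3.
#'
#' @param query,subject Sequence records: lists or one-row tibbles with
#'   `id` and `seq`.
#' @param scheme A [scoring_scheme()].
#' @param max_evalue E-value ceiling; `Inf` disables the cut.
#' @param min_segment_aa Minimum segment length (residues) considered for
#'   alignment; short inter-stop fragments below this are skipped.
#' @return A list of class `translated_hit` with ids, frames, aligned
#'   strings, `raw_score`, `evalue` and 1-based inclusive nucleotide spans
#'   `query_span_nt`, `subject_span_nt` on the original strands, or `NULL`.
#' @export
best_translated_hit <- function(query, subject, scheme = scoring_scheme(),
                                max_evalue = Inf, min_segment_aa = 8L) {
  qsegs <- frame_segments(query$seq, min_segment_aa)
  ssegs <- frame_segments(subject$seq, min_segment_aa)
  if (!length(qsegs$segment) || !length(ssegs$segment)) return(NULL)
  # one vectorized elementwise call over every segment-pair combination;
  # combo order (query index fastest) fixes the tie-break to the earliest
  # frame pair
  combos <- expand.grid(i = seq_along(qsegs$segment),
                        j = seq_along(ssegs$segment))
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(qsegs$segment[combos$i]),
    Biostrings::AAStringSet(ssegs$segment[combos$j]),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE
  )
  k <- which.max(scores)
  best <- list(score = scores[k], i = combos$i[k], j = combos$j[k])
  if (best$score <= 0) return(NULL)
  m <- floor(nchar(query$seq) / 3)
  n <- floor(nchar(subject$seq) / 3)
  ev <- evalue_from_score(best$score, scheme, m, n)
  if (ev > max_evalue) return(NULL)
  al <- local_align(qsegs$segment[best$i], ssegs$segment[best$j], scheme)
  structure(
    list(
      query_id = query$id, subject_id = subject$id,
      query_frame = qsegs$frame[best$i], subject_frame = ssegs$frame[best$j],
      aligned_query = al$aligned_query, aligned_subject = al$aligned_subject,
      raw_score = al$score, evalue = ev,
      query_span_nt = aa_span_to_nt(
        qsegs$frame[best$i], qsegs$offset[best$i],
        al$query_span_aa[1], al$query_span_aa[2], nchar(query$seq)
      ),
      subject_span_nt = aa_span_to_nt(
        ssegs$frame[best$j], ssegs$offset[best$j],
        al$subject_span_aa[1], al$subject_span_aa[2], nchar(subject$seq)
      )
    ),
    class = "translated_hit"
  )
}
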