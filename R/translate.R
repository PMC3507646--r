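# Six-frame translation under the standard genetic code.

# cached codon -> residue lookup over the full IUPAC alphabet: an ambiguous
# codon translates to its unique residue when every resolution agrees,
# otherwise to X
fuzzy_codon_table <- function() {
  if (is.null(the$fuzzy_codons)) {
    gc <- Biostrings::GENETIC_CODE
    iupac <- Biostrings::IUPAC_CODE_MAP[IUPAC_NT]
    combos <- expand.grid(b1 = IUPAC_NT, b2 = IUPAC_NT, b3 = IUPAC_NT,
                          stringsAsFactors = FALSE)
    aa <- vapply(seq_len(nrow(combos)), function(k) {
      ex <- expand.grid(
        strsplit(iupac[[combos$b1[k]]], "")[[1]],
        strsplit(iupac[[combos$b2[k]]], "")[[1]],
        strsplit(iupac[[combos$b3[k]]], "")[[1]],
        stringsAsFactors = FALSE
      )
      res <- unique(gc[paste0(ex[[1]], ex[[2]], ex[[3]])])
      if (length(res) == 1) res else "X"
    }, "")
    the$fuzzy_codons <- setNames(aa, paste0(combos$b1, combos$b2, combos$b3))
  }
  the$fuzzy_codons
}

translate_frame <- function(seq, offset) {
  n <- nchar(seq) - offset
  n <- n - n %% 3L
  if (n < 3L) return("")
  starts <- seq(offset + 1L, offset + n, by = 3L)
  paste(fuzzy_codon_table()[substring(seq, starts, starts + 2L)],
        collapse = "")
}

REVCOMP_MAP <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y", Y = "R", S = "S",
  W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B"
)

revcomp <- function(seq) {
  paste(rev(REVCOMP_MAP[strsplit(seq, "")[[1]]]), collapse = "")
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1/+2/+3 read the given strand with offsets 0/1/2; frames
#' -1/-2/-3 read the reverse complement the same way. Trailing partial
#' codons are dropped. Ambiguity codes translate to `X` unless every
#' resolution of the codon encodes the same residue; stop codons are
#' rendered `*`.
#'
#' @param seq A nucleotide string (IUPAC codes) of length >= 3.
#' @return A tibble with columns `frame` (integer in +1..+3, -1..-3) and
#'   `peptide`.
#' @examples
#' six_frame_translate("ATGGCC") # frame +1 gives "MA", frame -1 "GH"
#' @export
six_frame_translate <- function(seq) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  if (nchar(seq) < 3) abort("sequence must be at least 3 nt long")
  rc <- revcomp(seq)
  tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    peptide = c(
      vapply(0:2, function(o) translate_frame(seq, o), ""),
      vapply(0:2, function(o) translate_frame(rc, o), "")
    )
  )
}
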