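# Residue scoring: BLOSUM62 access, scoring schemes, Karlin-Altschul E-values.

the <- new.env(parent = emptyenv())

#' The 20 standard amino-acid one-letter codes
#' @keywords internal
#' @noRd
STANDARD_AA <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' BLOSUM62 substitution matrix
#'
#' Returns the NCBI-standard integer BLOSUM62 matrix (as shipped with
#' Biostrings), restricted to the 20 standard residues plus `X` and the
#' stop symbol `*`. Positive off-diagonal entries mark biochemically
#' conservative replacements — the "+" of a protein-search midline.
#'
#' @return An integer matrix with row/column names over the 22 symbols.
#' @examples
#' blosum62()["K", "R"] # +2, a conservative substitution
#' blosum62()["L", "D"] # -4, a radical one
#' @export
blosum62 <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    keep <- c(STANDARD_AA, "X", "*")
    the$blosum62 <- e$BLOSUM62[keep, keep]
  }
  the$blosum62
}

#' Scoring scheme for translated local alignment
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw scores to E-values.
#' Defaults follow the common protein-search configuration:
#' BLOSUM62 with gap open 11 / extend 1, and the gapped-BLOSUM62
#' constants lambda = 0.267, K = 0.041.
#'
#' @param matrix Substitution matrix (symmetric over the standard
#'   residues); defaults to [blosum62()].
#' @param gap_open,gap_extend Positive integer gap penalties. A gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters for `E = K m n exp(-lambda S)`.
#' @param search_space Optional fixed effective search space `m * n`;
#'   when `NULL`, the product of the supplied sequence lengths is used.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041, search_space = NULL) {
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)))
  aa <- intersect(rownames(matrix), STANDARD_AA)
  if (!isTRUE(all(matrix[aa, aa] == t(matrix[aa, aa])))) {
    abort("substitution matrix must be symmetric over the standard residues")
  }
  if (gap_open <= 0 || gap_extend <= 0) {
    abort("gap penalties must be positive")
  }
  structure(
    list(
      matrix = matrix, gap_open = as.integer(gap_open),
      gap_extend = as.integer(gap_extend),
      lambda = lambda, K = K, search_space = search_space
    ),
    class = "scoring_scheme"
  )
}

#' E-value from a raw alignment score
#'
#' Karlin-Altschul conversion `E = K * m * n * exp(-lambda * S)`.
#' E is monotone decreasing in the score and linear in the search
#' space `m * n`.
#'
#' @param raw_score Raw alignment score.
#' @param scheme A [scoring_scheme()].
#' @param query_len,db_len Positive effective lengths (residues).
#' @return A positive E-value (numeric).
#' @examples
#' sc <- scoring_scheme()
#' evalue_from_score(100, sc, 100, 100)
#' @export
evalue_from_score <- function(raw_score, scheme, query_len, db_len) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    abort("sequence lengths must be positive")
  }
  mn <- scheme$search_space %||% (as.numeric(query_len) * as.numeric(db_len))
  scheme$K * mn * exp(-scheme$lambda * raw_score)
}

# residues with at least one conservative partner (BLOSUM62 > 0 off-diagonal);
# C, G and P have none and so can never receive a conservative substitution
conservative_partners <- function() {
  if (is.null(the$cons_partners)) {
    m <- blosum62()[STANDARD_AA, STANDARD_AA]
    the$cons_partners <- lapply(setNames(STANDARD_AA, STANDARD_AA), function(a) {
      STANDARD_AA[m[a, ] > 0 & STANDARD_AA != a]
    })
  }
  the$cons_partners
}

radical_partners <- function() {
  if (is.null(the$rad_partners)) {
    m <- blosum62()[STANDARD_AA, STANDARD_AA]
    the$rad_partners <- lapply(setNames(STANDARD_AA, STANDARD_AA), function(a) {
      STANDARD_AA[m[a, ] <= 0 & STANDARD_AA != a]
    })
  }
  the$rad_partners
}
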