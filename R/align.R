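#' Affine gap penalties
#'
#' Gap costs for pairwise alignment. The defaults (10 to open, 1 to extend)
#' are the values used throughout the delta-score computation. Two affine
#' conventions are supported because published descriptions of "open 10,
#' extend 1" are ambiguous about whether the first gapped residue pays the
#' opening cost alone:
#'
#' * `"first_residue_costs_open_only"` (default, classic Gotoh): a length-L
#'   gap costs `open + (L - 1) * extend`.
#' * `"open_plus_per_residue"`: a length-L gap costs `open + L * extend`.
#'
#' @param open Non-negative integer gap opening penalty.
#' @param extend Non-negative integer gap extension penalty; must not exceed
#'   `open`.
#' @param convention Affine convention, see above.
#' @return An object of class `gap_penalties`.
#' @export
gap_penalties <- function(open = 10L, extend = 1L,
                          convention = c("first_residue_costs_open_only",
                                         "open_plus_per_residue")) {
  convention <- match.arg(convention)
  open <- as.integer(open); extend <- as.integer(extend)
  stopifnot(!is.na(open), !is.na(extend), open >= extend, extend >= 0L)
  structure(list(open = open, extend = extend, convention = convention),
            class = "gap_penalties")
}

# cost of the first residue of a gap under the configured convention
gap_first_cost <- function(g) {
  if (g$convention == "first_residue_costs_open_only") g$open
  else g$open + g$extend
}

# encode residues as 0-based indices into the matrix rows
encode_residues <- function(x, m) {
  chars <- seq_chars(x)
  idx <- match(chars, rownames(m$scores))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("residue(s) not scorable under ", m$name, ": ",
         paste(bad, collapse = ", "))
  }
  idx - 1L
}

# score and identity count of the optimal semi-global alignment
align_pair <- function(a, b, m = blosum62(), g = gap_penalties()) {
  a <- as_protein_seq(a); b <- as_protein_seq(b)
  gotoh_semiglobal(encode_residues(a, m), encode_residues(b, m),
                   m$scores, gap_first_cost(g), g$extend)
}

#' Semi-global (free end-gap) alignment score
#'
#' Computes the optimal score of a semi-global pairwise alignment: a global
#' alignment in which gaps at either end of either sequence carry no
#' penalty (overlap alignment). Internal gaps are charged affine costs per
#' [gap_penalties()]; matched pairs are scored under the substitution
#' matrix. Only the score is computed (three-state Gotoh dynamic program,
#' integer arithmetic, no traceback); this is the `S(a, b)` that delta
#' scores are built from.
#'
#' @param a,b [protein_seq] objects (or plain residue strings).
#' @param m A [subst_matrix]; defaults to [blosum62()].
#' @param g A [gap_penalties] object.
#' @return Integer alignment score.
#' @examples
#' semiglobal_score("GG", "GG")       # 12
#' semiglobal_score("HEAGAWGHEE", "PAWHEAE")
#' @export
semiglobal_score <- function(a, b, m = blosum62(), g = gap_penalties()) {
  as.integer(align_pair(a, b, m, g)$score)
}

#' @describeIn semiglobal_score Self-alignment score `S(a, a)`; for a
#'   diagonal-dominant matrix and positive gap costs this is the sum of the
#'   diagonal scores of `a`'s residues.
#' @export
self_score <- function(a, m = blosum62(), g = gap_penalties()) {
  semiglobal_score(a, a, m, g)
}
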