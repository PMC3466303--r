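#' Read an NCBI-format substitution matrix
#'
#' Parses the standard plain-text square matrix format used by the NCBI
#' toolkit ('#'-prefixed comments, one header row of residue symbols, one
#' labelled row per residue). The `*` (stop/minimum) row and column, if
#' present, are dropped. The matrix is checked for symmetry, and for the
#' diagonal-dominance property on the 20 standard residues (each residue's
#' self-score is the maximum of its row), which several score invariants in
#' this package rely on; violations on the standard alphabet raise an error,
#' violations restricted to ambiguity rows are tolerated (the canonical
#' BLOSUM62 X row has off-diagonal maxima).
#'
#' @param path Path to the matrix file.
#' @param name Name recorded on the returned object.
#' @return An object of class `subst_matrix`: a list with fields `name` and
#'   `scores` (integer matrix with residue dimnames).
#' @export
read_subst_matrix <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m))
    stop("substitution matrix is not square: ", path)
  rownames(m) <- colnames(m)
  keep <- setdiff(colnames(m), "*")
  m <- m[keep, keep, drop = FALSE]
  storage.mode(m) <- "integer"
  if (!identical(m, t(m)))
    stop("substitution matrix is not symmetric: ", path)
  std <- intersect(rownames(m), AA_STANDARD)
  for (r in std) {
    if (m[r, r] < max(m[r, std]))
      stop("diagonal entry for ", r, " is not the row maximum; ",
           "matrix unsuitable for delta scoring: ", path)
  }
  structure(list(name = name, scores = m), class = "subst_matrix")
}

#' The BLOSUM62 substitution matrix
#'
#' Loads (and caches) the canonical NCBI BLOSUM62 matrix bundled with the
#' package, including the B/Z/X ambiguity rows. This is the default matrix
#' for all alignment scoring. Alternative matrices in the same text format
#' can be loaded with [read_subst_matrix()].
#'
#' @return A `subst_matrix`.
#' @examples
#' m <- blosum62()
#' subst_score(m, "G", "G")  # 6
#' subst_score(m, "C", "G")  # -3
#' @export
blosum62 <- function() {
  if (is.null(.proveanr_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "proveanr",
                        mustWork = TRUE)
    .proveanr_cache$blosum62 <- read_subst_matrix(path, name = "BLOSUM62")
  }
  .proveanr_cache$blosum62
}

#' @rdname blosum62
#' @param m A `subst_matrix`.
#' @param a,b Single residue characters.
#' @export
subst_score <- function(m, a, b) {
  stopifnot(inherits(m, "subst_matrix"))
  s <- m$scores
  if (!a %in% rownames(s) || !b %in% rownames(s))
    stop("residue pair (", a, ", ", b, ") not scorable under ", m$name)
  s[a, b]
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat(sprintf("<subst_matrix> %s (%d x %d)\n", x$name,
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}
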