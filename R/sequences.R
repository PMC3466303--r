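#' Amino acid alphabet
#'
#' Residue symbols accepted by the package: the 20 standard amino acids plus
#' the ambiguity codes B (Asx), Z (Glx) and X (any). The rare translated
#' residues U (Sec) and O (Pyl) are rejected because the bundled substitution
#' matrices carry no scores for them.
#'
#' @format A character vector of length 23.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

AA_STANDARD <- AA_ALPHABET[1:20]

#' Construct a protein sequence
#'
#' A `protein_seq` is an identified amino acid string: the query sequence or
#' one supporting homolog. Residues are case-normalized to upper case and
#' checked against [AA_ALPHABET]; sequences containing the ambiguity codes
#' B/Z/X are accepted and flagged via the `"extended"` attribute.
#'
#' @param residues Single character string of amino acid residues (or a
#'   character vector of single residues, which is collapsed).
#' @param id Sequence identifier.
#' @return An object of class `protein_seq` with fields `id` and `residues`.
#' @examples
#' q <- protein_seq("MKTAYIAKQR", id = "query")
#' seq_length(q)
#' @export
protein_seq <- function(residues, id = "seq") {
  if (length(residues) > 1L) residues <- paste(residues, collapse = "")
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("protein sequence must be non-empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    if (any(bad %in% c("U", "O")))
      stop("residues U (selenocysteine) / O (pyrrolysine) are not scorable ",
           "under the bundled substitution matrices; found in '", id, "'")
    stop("invalid residue symbol(s) in '", id, "': ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(id = as.character(id), residues = residues),
    extended = any(chars %in% c("B", "Z", "X")),
    class = "protein_seq"
  )
}

#' @rdname protein_seq
#' @param x A `protein_seq`.
#' @export
seq_length <- function(x) nchar(as_protein_seq(x)$residues)

#' @export
print.protein_seq <- function(x, ...) {
  r <- x$residues
  if (nchar(r) > 60) r <- paste0(substr(r, 1, 57), "...")
  cat(sprintf("<protein_seq> %s (%d aa)\n%s\n", x$id, seq_length(x), r))
  invisible(x)
}

#' @export
as.character.protein_seq <- function(x, ...) x$residues

as_protein_seq <- function(x, id = "seq") {
  if (inherits(x, "protein_seq")) return(x)
  protein_seq(x, id = id)
}

seq_chars <- function(x) strsplit(as_protein_seq(x)$residues, "", fixed = TRUE)[[1]]

#' Read and write protein FASTA files
#'
#' Thin wrappers around Biostrings' FASTA support returning/accepting lists
#' of [protein_seq] objects. Identifiers are truncated at the first
#' whitespace, matching common BLAST/CD-HIT usage.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()` returns a named list of `protein_seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- mapply(function(s, id) protein_seq(s, id = id),
                 as.character(set), ids, SIMPLIFY = FALSE)
  names(seqs) <- ids
  seqs
}

#' @rdname read_fasta
#' @param seqs A `protein_seq` or list of them.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "protein_seq")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, function(s) s$residues, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
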