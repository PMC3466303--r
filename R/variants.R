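#' Protein variants
#'
#' A `protein_variant` describes one in-frame protein change against a query
#' sequence, with 1-based inclusive coordinates:
#'
#' * substitution: one residue replaced by one residue (`|ref| = |alt| = 1`);
#' * deletion: one or more residues removed (`|alt| = 0`);
#' * insertion: residues added after position `position` (`|ref| = 0`;
#'   position 0 inserts before the first residue);
#' * replacement: a run of residues replaced by a different run
#'   (`|ref| >= 1`, `|alt| >= 1`, not a substitution).
#'
#' Variants with `|ref|` or `|alt|` above 6 residues are accepted with a
#' warning: the scoring scheme is length-agnostic but has been validated on
#' variants of up to 6 amino acids.
#'
#' @param kind One of `"substitution"`, `"deletion"`, `"insertion"`,
#'   `"replacement"`.
#' @param position 1-based position of the first reference residue (for
#'   insertions, the residue the insert follows; 0 allowed).
#' @param ref Reference residues (empty string for insertions).
#' @param alt Alternate residues (empty string for deletions).
#' @return An object of class `protein_variant`.
#' @examples
#' variant("substitution", 12, "G", "C")
#' variant("deletion", 508, "F", "")
#' @export
variant <- function(kind, position, ref = "", alt = "") {
  kind <- match.arg(kind, c("substitution", "deletion", "insertion",
                            "replacement"))
  position <- as.integer(position)
  ref <- toupper(ref); alt <- toupper(alt)
  nr <- nchar(ref); na <- nchar(alt)
  ok <- switch(kind,
    substitution = nr == 1L && na == 1L,
    deletion     = nr >= 1L && na == 0L,
    insertion    = nr == 0L && na >= 1L,
    replacement  = nr >= 1L && na >= 1L && !(nr == 1L && na == 1L))
  if (!ok)
    stop("ref/alt lengths (", nr, ", ", na, ") inconsistent with kind '",
         kind, "'")
  if (kind == "insertion") {
    if (position < 0L) stop("insertion position must be >= 0")
  } else if (position < 1L) {
    stop("position must be >= 1")
  }
  for (s in c(ref, alt)) {
    if (nzchar(s)) as_protein_seq(s) # residue validation
  }
  if (nr > 6L || na > 6L)
    warning("variant longer than 6 residues: outside the validated regime, ",
            "scored anyway", call. = FALSE)
  structure(list(kind = kind, position = position, ref = ref, alt = alt),
            class = "protein_variant")
}

#' @export
print.protein_variant <- function(x, ...) {
  cat(sprintf("<protein_variant> %s (%s)\n", format_variant(x), x$kind))
  invisible(x)
}

# check ref residues (and coordinates) against the query; stop on mismatch
validate_variant <- function(v, query) {
  query <- as_protein_seq(query)
  L <- seq_length(query)
  if (v$kind == "insertion") {
    if (v$position > L)
      stop("insertion position ", v$position, " beyond sequence length ", L)
    return(invisible(v))
  }
  to <- v$position + nchar(v$ref) - 1L
  if (to > L)
    stop("variant window [", v$position, ", ", to,
         "] beyond sequence length ", L)
  found <- substr(query$residues, v$position, to)
  if (!identical(found, v$ref))
    stop("reference mismatch at position ", v$position, ": variant says '",
         v$ref, "' but query '", query$id, "' has '", found,
         "' (coordinate or sequence-version problem?)")
  invisible(v)
}

#' Parse an HGVS-like protein variant string
#'
#' Accepted grammar (residues are one-letter codes, positions 1-based):
#'
#' * `G12C` - substitution;
#' * `F508del`, `K10_L12del` - deletion of one residue or a range;
#' * `K10_E11insGS` - insertion between two adjacent residues
#'   (`0_M1insGS` inserts before the first residue; after the last residue
#'   the right flank is written without a residue letter, e.g. `K40_41insGS`
#'   for a 40-residue query);
#' * `A5delinsTR`, `A5_G6delinsTR` - replacement of one residue or a range.
#'
#' All flanking/reference residues named in the string are checked against
#' the query; a mismatch signals a coordinate or sequence-version problem
#' and raises an error.
#'
#' @param text Variant string.
#' @param query The query [protein_seq].
#' @return A validated [variant()].
#' @examples
#' q <- protein_seq("MKTAYIAKQR", "q")
#' parse_variant("K2A", q)
#' parse_variant("T3_A4del", q)
#' @export
parse_variant <- function(text, query) {
  query <- as_protein_seq(query)
  text <- trimws(text)
  qres <- function(i) substr(query$residues, i, i)

  v <- NULL
  if (grepl("^([A-Za-z]\\d+)(_[A-Za-z]\\d+)?delins[A-Za-z]+$", text)) {
    mm <- regmatches(text, regexec(
      "^([A-Za-z])(\\d+)(?:_([A-Za-z])(\\d+))?delins([A-Za-z]+)$", text))[[1]]
    from <- as.integer(mm[3])
    to <- if (nzchar(mm[4])) as.integer(mm[5]) else from
    if (to < from) stop("descending range in variant string: ", text)
    if (to > seq_length(query))
      stop("variant window [", from, ", ", to, "] beyond sequence length ",
           seq_length(query))
    ref <- substr(query$residues, from, to)
    v <- variant(if (nchar(ref) == 1L && nchar(mm[6]) == 1L) "substitution"
                 else "replacement", from, ref, toupper(mm[6]))
    check_flank(text, query, toupper(mm[2]), from)
    if (nzchar(mm[4])) check_flank(text, query, toupper(mm[4]), to)
  } else if (grepl("del$", text)) {
    mm <- regmatches(text, regexec(
      "^([A-Za-z])(\\d+)(?:_([A-Za-z])(\\d+))?del$", text))[[1]]
    if (!length(mm)) stop("cannot parse variant string: ", text)
    from <- as.integer(mm[3])
    to <- if (nzchar(mm[4])) as.integer(mm[5]) else from
    if (to < from) stop("descending range in variant string: ", text)
    if (to > seq_length(query))
      stop("variant window [", from, ", ", to, "] beyond sequence length ",
           seq_length(query))
    v <- variant("deletion", from, substr(query$residues, from, to), "")
    check_flank(text, query, toupper(mm[2]), from)
    if (nzchar(mm[4])) check_flank(text, query, toupper(mm[4]), to)
  } else if (grepl("ins", text, fixed = TRUE)) {
    mm <- regmatches(text, regexec(
      "^(?:([A-Za-z])(\\d+)|0)_([A-Za-z]?)(\\d+)ins([A-Za-z]+)$", text))[[1]]
    if (!length(mm)) stop("cannot parse variant string: ", text)
    ntm <- !nzchar(mm[2]) # N-terminal "0_X1ins..."
    left <- if (ntm) 0L else as.integer(mm[3])
    right <- as.integer(mm[5])
    if (right != left + 1L)
      stop("insertion flanks must be adjacent positions: ", text)
    if (!ntm) check_flank(text, query, toupper(mm[2]), left)
    if (nzchar(mm[4])) check_flank(text, query, toupper(mm[4]), right)
    else if (right != seq_length(query) + 1L)
      stop("insertion flank residue missing in variant string: ", text)
    v <- variant("insertion", left, "", toupper(mm[6]))
  } else {
    mm <- regmatches(text, regexec("^([A-Za-z])(\\d+)([A-Za-z])$", text))[[1]]
    if (!length(mm)) stop("cannot parse variant string: ", text)
    v <- variant("substitution", as.integer(mm[3]), toupper(mm[2]),
                 toupper(mm[4]))
  }
  validate_variant(v, query)
  v
}

check_flank <- function(text, query, aa, pos) {
  if (pos < 1L || pos > seq_length(query))
    stop("position ", pos, " beyond sequence length ", seq_length(query),
         " in variant string: ", text)
  found <- substr(query$residues, pos, pos)
  if (!identical(found, aa))
    stop("reference mismatch at position ", pos, ": variant string '", text,
         "' says '", aa, "' but query '", query$id, "' has '", found, "'")
  invisible(TRUE)
}

#' @rdname parse_variant
#' @param v A `protein_variant`.
#' @return `format_variant()` returns the canonical string form, the inverse
#'   of `parse_variant()` on valid variants.
#' @export
format_variant <- function(v, query = NULL) {
  stopifnot(inherits(v, "protein_variant"))
  p <- v$position
  last <- function(s) substr(s, nchar(s), nchar(s))
  switch(v$kind,
    substitution = paste0(v$ref, p, v$alt),
    deletion = if (nchar(v$ref) == 1L) paste0(v$ref, p, "del")
               else paste0(substr(v$ref, 1, 1), p, "_", last(v$ref),
                           p + nchar(v$ref) - 1L, "del"),
    replacement = if (nchar(v$ref) == 1L)
                    paste0(v$ref, p, "delins", v$alt)
                  else paste0(substr(v$ref, 1, 1), p, "_", last(v$ref),
                              p + nchar(v$ref) - 1L, "delins", v$alt),
    insertion = {
      if (is.null(query))
        stop("formatting an insertion requires the query sequence ",
             "(flanking residues appear in the string)")
      query <- as_protein_seq(query)
      leftaa <- if (p == 0L) "0" else
        paste0(substr(query$residues, p, p), p)
      # C-terminal insertion: right flank is past the last residue
      rightaa <- substr(query$residues, p + 1L, p + 1L)
      paste0(leftaa, "_", rightaa, p + 1L, "ins", v$alt)
    })
}

#' Apply a variant to the query sequence
#'
#' Produces the variant sequence Q' by splicing `alt` in place of `ref` at
#' the variant position (for insertions and deletions the residues are
#' inserted into, or removed from, the query before any alignment is
#' performed). Residues outside the edited window are unchanged and
#' `nchar(Q') - nchar(Q) = nchar(alt) - nchar(ref)`.
#'
#' @inheritParams parse_variant
#' @param v A validated [variant()].
#' @return A [protein_seq] for the variant sequence.
#' @examples
#' q <- protein_seq("ACDEF", "q")
#' as.character(apply_variant(q, variant("deletion", 3, "D", "")))  # "ACEF"
#' @export
apply_variant <- function(query, v) {
  query <- as_protein_seq(query)
  validate_variant(v, query)
  res <- query$residues
  left <- if (v$kind == "insertion") substr(res, 1, v$position)
          else substr(res, 1, v$position - 1L)
  right_from <- if (v$kind == "insertion") v$position + 1L
                else v$position + nchar(v$ref)
  right <- substr(res, right_from, nchar(res))
  out <- paste0(left, v$alt, right)
  if (!nzchar(out))
    stop("variant deletes the entire sequence; nothing to align")
  protein_seq(out, id = paste0(query$id, ":", v$kind, v$position))
}

#' @describeIn apply_variant The identity substitution at `position`
#'   (ref = alt = the query residue); applying it returns the query
#'   unchanged and its delta score is 0 against any subject.
#' @param position 1-based query position.
#' @export
null_variant <- function(query, position) {
  query <- as_protein_seq(query)
  stopifnot(position >= 1L, position <= seq_length(query))
  aa <- substr(query$residues, position, position)
  variant("substitution", position, aa, aa)
}

#' Read a variant table
#'
#' Reads a TSV with columns `variant_string` and optionally `label`
#' (`deleterious` / `neutral` / `unknown`); lines starting with `#` are
#' ignored. Each string is parsed and validated against the query.
#'
#' @param path TSV path.
#' @param query The query [protein_seq].
#' @return A list of records, each `list(variant, label, string)`.
#' @export
read_variant_tsv <- function(path, query) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!"variant_string" %in% names(df))
    stop("variant TSV needs a 'variant_string' column: ", path)
  labels <- if ("label" %in% names(df)) df$label else
    rep("unknown", nrow(df))
  bad <- setdiff(unique(labels), c("deleterious", "neutral", "unknown"))
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    list(variant = parse_variant(df$variant_string[i], query),
         label = labels[i], string = df$variant_string[i])
  })
}

#' @rdname read_variant_tsv
#' @param records List of records as returned by `read_variant_tsv()` (or
#'   built by [generate_labeled_variants()]).
#' @export
write_variant_tsv <- function(records, path, query = NULL) {
  df <- data.frame(
    variant_string = vapply(records, function(r) {
      if (!is.null(r$string)) r$string else format_variant(r$variant, query)
    }, ""),
    label = vapply(records, function(r) r$label %||% "unknown", ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
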