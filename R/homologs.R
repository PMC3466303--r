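#' Homology-search hits
#'
#' A `homolog_hit` pairs a candidate supporting sequence with the E-value
#' (and optionally bit score) reported by the upstream homology search.
#' External search tools are never invoked by this package; hits are either
#' built directly from a FASTA of pre-collected homologs or parsed from the
#' standard 12-column BLAST tabular format with [read_hit_table()].
#'
#' @param sequence A [protein_seq].
#' @param evalue Search E-value (`NA` if unknown).
#' @param bitscore Bit score (`NA` if unknown).
#' @export
homolog_hit <- function(sequence, evalue = NA_real_, bitscore = NA_real_) {
  structure(list(sequence = as_protein_seq(sequence),
                 evalue = as.numeric(evalue),
                 bitscore = as.numeric(bitscore)),
            class = "homolog_hit")
}

#' Filter and deduplicate homology hits
#'
#' Keeps hits with E-value at or below the threshold (default 0.1, the
#' value used when collecting supporting sequences). Hits lacking an
#' E-value pass the filter but are flagged with a message. Exact duplicate
#' sequences are collapsed, keeping the best (smallest) E-value.
#'
#' @param hits List of [homolog_hit] objects.
#' @param e_threshold E-value cutoff.
#' @return Filtered list of `homolog_hit`.
#' @export
filter_hits <- function(hits, e_threshold = 0.1) {
  stopifnot(is.list(hits))
  if (!length(hits)) return(hits)
  ev <- vapply(hits, function(h) h$evalue, 0)
  if (anyNA(ev))
    message(sum(is.na(ev)), " hit(s) lack an E-value; passed unfiltered")
  keep <- is.na(ev) | ev <= e_threshold
  hits <- hits[keep]
  if (!length(hits)) return(hits)
  res <- vapply(hits, function(h) h$sequence$residues, "")
  ev <- vapply(hits, function(h) h$evalue, 0)
  ord <- order(res, ifelse(is.na(ev), Inf, ev))
  hits <- hits[ord][!duplicated(res[ord])]
  hits[order(match(vapply(hits, function(h) h$sequence$residues, ""), res))]
}

#' Pairwise sequence identity
#'
#' Fraction of identical aligned residue pairs in the optimal semi-global
#' alignment, divided by the length of the shorter sequence (the CD-HIT
#' convention). Among alignments that tie on score, the one with the most
#' identities is used, which makes the value deterministic.
#'
#' @inheritParams semiglobal_score
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAA")  # 1
#' pairwise_identity("AAAA", "TTTT")  # 0
#' @export
pairwise_identity <- function(a, b, m = blosum62(), g = gap_penalties()) {
  a <- as_protein_seq(a); b <- as_protein_seq(b)
  r <- align_pair(a, b, m, g)
  r$identities / min(seq_length(a), seq_length(b))
}

new_cluster <- function(members, representative, query_similarity = NA_real_) {
  structure(list(members = members, representative = representative,
                 query_similarity = query_similarity),
            class = "seq_cluster")
}

#' @export
print.seq_cluster <- function(x, ...) {
  cat(sprintf("<seq_cluster> rep %s, %d member(s)\n",
              x$representative$id, length(x$members)))
  invisible(x)
}

#' Greedy identity clustering of sequences
#'
#' Removes redundancy among homologs by greedy incremental clustering in the
#' style of CD-HIT: sequences are processed longest-first (ties broken
#' lexicographically by residues, then by id, for reproducibility); each
#' sequence joins the first existing cluster whose representative it matches
#' at or above the identity threshold, otherwise it founds a new cluster
#' and becomes its representative. The resulting clusters partition the
#' input.
#'
#' @param seqs Non-empty list of [protein_seq].
#' @param identity_threshold Identity fraction (default 0.80).
#' @inheritParams semiglobal_score
#' @return List of `seq_cluster` objects.
#' @export
cluster_sequences <- function(seqs, identity_threshold = 0.80,
                              m = blosum62(), g = gap_penalties()) {
  stopifnot(is.list(seqs), length(seqs) >= 1L)
  seqs <- lapply(seqs, as_protein_seq)
  lens <- vapply(seqs, seq_length, 0L)
  res <- vapply(seqs, function(s) s$residues, "")
  ids <- vapply(seqs, function(s) s$id, "")
  ord <- order(-lens, res, ids)
  clusters <- list()
  for (i in ord) {
    s <- seqs[[i]]
    placed <- FALSE
    for (k in seq_along(clusters)) {
      if (pairwise_identity(s, clusters[[k]]$representative, m, g) >=
          identity_threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, list(s))
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- new_cluster(list(s), s)
  }
  clusters
}

#' Build the supporting sequence set
#'
#' Assembles the clustered homolog set that a variant is scored against.
#' The query is added to the clustering input (so a prediction is always
#' possible, even with no homologs at all: the set degenerates to the query
#' alone). Sequences are clustered at the identity threshold, clusters are
#' ranked by similarity of their representative to the query (semi-global
#' alignment score, descending; ties broken by larger cluster, then by
#' representative id), the query's own cluster is forced to rank first, and
#' the top `max_clusters` clusters are retained.
#'
#' @param query The query [protein_seq].
#' @param homologs List of [protein_seq] (may be empty), e.g. from
#'   [read_fasta()] or `filter_hits()` output sequences.
#' @param identity_threshold Clustering identity (default 0.80).
#' @param max_clusters Cluster-count cap (default 45).
#' @inheritParams semiglobal_score
#' @return An object of class `supporting_set`: list with `clusters`,
#'   `identity_threshold`, `max_clusters`, `query`.
#' @examples
#' q <- protein_seq("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "q")
#' ss <- build_supporting_set(q, list())
#' n_supporting_sequences(ss)  # 1: the query itself
#' @export
build_supporting_set <- function(query, homologs = list(),
                                 identity_threshold = 0.80,
                                 max_clusters = 45L,
                                 m = blosum62(), g = gap_penalties()) {
  query <- as_protein_seq(query)
  stopifnot(max_clusters >= 1L)
  homologs <- lapply(homologs, as_protein_seq)
  clusters <- cluster_sequences(c(list(query), homologs),
                                identity_threshold, m, g)
  has_query <- vapply(clusters, function(cl) {
    any(vapply(cl$members, function(s)
      identical(s$residues, query$residues) && identical(s$id, query$id),
      TRUE))
  }, TRUE)
  qi <- which(has_query)[1]
  sim <- vapply(clusters, function(cl)
    as.numeric(semiglobal_score(cl$representative, query, m, g)), 0)
  for (k in seq_along(clusters)) clusters[[k]]$query_similarity <- sim[k]
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  reps <- vapply(clusters, function(cl) cl$representative$id, "")
  rest <- setdiff(order(-sim, -sizes, reps), qi)
  keep <- c(qi, rest)[seq_len(min(length(clusters), max_clusters))]
  structure(list(clusters = clusters[keep],
                 identity_threshold = identity_threshold,
                 max_clusters = as.integer(max_clusters),
                 query = query),
            class = "supporting_set")
}

#' @rdname build_supporting_set
#' @param sset A `supporting_set`.
#' @export
n_clusters <- function(sset) length(sset$clusters)

#' @rdname build_supporting_set
#' @export
n_supporting_sequences <- function(sset) {
  sum(vapply(sset$clusters, function(cl) length(cl$members), 0L))
}

#' @export
print.supporting_set <- function(x, ...) {
  cat(sprintf(paste0("<supporting_set> %d cluster(s), %d sequence(s) ",
                     "(identity >= %.0f%%, cap %d)\n"),
              n_clusters(x), n_supporting_sequences(x),
              100 * x$identity_threshold, x$max_clusters))
  invisible(x)
}

#' Read a BLAST tabular hit file
#'
#' Parses the standard 12-column BLAST tabular output (`-outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) and cross-references subject ids against a FASTA-derived
#' sequence list.
#'
#' @param path Tabular hit file.
#' @param seqs Named list of [protein_seq] (names = sequence ids), e.g.
#'   from [read_fasta()].
#' @return List of [homolog_hit].
#' @export
read_hit_table <- function(path, seqs) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  hits <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop("line ", i, ": expected 12 tab-separated columns, got ",
           length(f), " in ", path)
    sid <- f[2]
    if (is.null(seqs[[sid]]))
      stop("line ", i, ": subject id '", sid,
           "' not present in the supplied sequences")
    hits[[i]] <- homolog_hit(seqs[[sid]], evalue = as.numeric(f[11]),
                             bitscore = as.numeric(f[12]))
  }
  hits
}

#' Read a CD-HIT .clstr file
#'
#' Optional ingestion of clusters produced by an external CD-HIT run, so
#' the exact upstream clustering can be reproduced. Representatives are the
#' members marked `*`.
#'
#' @param path `.clstr` file.
#' @param seqs Named list of [protein_seq].
#' @return List of `seq_cluster`.
#' @export
read_cdhit_clusters <- function(path, seqs) {
  lines <- readLines(path)
  clusters <- list()
  members <- list(); rep_id <- NULL
  flush <- function() {
    if (!length(members)) return()
    if (is.null(rep_id))
      stop("cluster without a '*' representative in ", path)
    clusters[[length(clusters) + 1L]] <<-
      new_cluster(members, seqs[[rep_id]])
    members <<- list(); rep_id <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">Cluster")) { flush(); next }
    mm <- regmatches(ln, regexec("aa, >(.+?)\\.{3}", ln))[[1]]
    if (length(mm) < 2) stop("line ", i, ": cannot parse member line in ",
                             path, ": ", ln)
    sid <- mm[2]
    if (is.null(seqs[[sid]]))
      stop("line ", i, ": member id '", sid,
           "' not present in the supplied sequences")
    members[[length(members) + 1L]] <- seqs[[sid]]
    if (grepl("\\*\\s*$", ln)) rep_id <- sid
  }
  flush()
  clusters
}
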