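#' Delta alignment score
#'
#' The change in semi-global alignment score against one subject sequence
#' caused by introducing a variant into the query:
#' `S(Q', subject) - S(Q, subject)`, where Q' is the variant sequence.
#' Negative values mean the variant reduced similarity to the subject and
#' are interpreted as functionally damaging; the variant residues are
#' spliced into Q before alignment, so substitutions, indels and
#' replacements are all scored by the same expression.
#'
#' @inheritParams apply_variant
#' @param subject A supporting [protein_seq].
#' @inheritParams semiglobal_score
#' @param base_score Optional precomputed `S(Q, subject)`; pass it when
#'   scoring many variants against the same subject to avoid recomputing
#'   the reference alignment.
#' @return Integer delta score (0 for a null variant).
#' @examples
#' q <- protein_seq("MKWVTFISLLLLFSSAYS", "q")
#' delta_score(q, parse_variant("W3C", q), q)
#' @export
delta_score <- function(query, v, subject, m = blosum62(),
                        g = gap_penalties(), base_score = NULL) {
  query <- as_protein_seq(query)
  if (is.null(base_score)) base_score <- semiglobal_score(query, subject, m, g)
  semiglobal_score(apply_variant(query, v), subject, m, g) - base_score
}

# S(Q, subject) for every member of every cluster, shaped like the clusters
baseline_scores <- function(sset, m, g) {
  lapply(sset$clusters, function(cl)
    vapply(cl$members, function(s)
      as.numeric(semiglobal_score(sset$query, s, m, g)), 0))
}

#' Classify a score as deleterious or neutral
#'
#' A variant is called deleterious when its final averaged delta score is
#' smaller than or equal to the threshold; the comparison is inclusive, so
#' a score exactly at the default threshold of -2.282 is deleterious.
#'
#' @param score Final averaged delta score(s).
#' @param threshold Decision threshold (default -2.282, selected on a large
#'   labeled human variant set to maximize the minimum of sensitivity and
#'   specificity).
#' @return Character vector, `"deleterious"` or `"neutral"`.
#' @export
classify <- function(score, threshold = -2.282) {
  stopifnot(all(is.finite(score)))
  ifelse(score <= threshold, "deleterious", "neutral")
}

#' The unbiased averaged delta score
#'
#' The package's central statistic. For one variant, a delta score is
#' computed against every sequence in the supporting set; the deltas are
#' averaged within each cluster, and the cluster means are averaged again
#' across clusters so that each cluster carries equal weight regardless of
#' size:
#' \deqn{score = \frac{1}{C} \sum_{c=1}^{C} \frac{1}{S_c}
#'       \sum_{i=1}^{S_c} \delta_{c,i}}
#' This two-level average prevents a large cluster of near-identical
#' database sequences from dominating the result. The score is thresholded
#' with [classify()].
#'
#' @inheritParams delta_score
#' @param sset A [build_supporting_set()] result.
#' @param threshold Decision threshold, see [classify()].
#' @param baseline Optional precomputed [baseline] list (internal caching
#'   contract used by [saturation_scan()] and [provean()]): the
#'   `S(Q, subject)` scores shaped like `sset$clusters`. Results are
#'   identical with or without it.
#' @return An object of class `provean_result`: list with `variant`,
#'   `score`, `cluster_means`, `n_clusters`, `n_sequences`, `prediction`,
#'   `threshold`.
#' @examples
#' q <- protein_seq("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "q")
#' ss <- build_supporting_set(q, list())
#' provean_score(q, parse_variant("K2A", q), ss)
#' @export
provean_score <- function(query, v, sset, m = blosum62(),
                          g = gap_penalties(), threshold = -2.282,
                          baseline = NULL) {
  query <- as_protein_seq(query)
  stopifnot(inherits(sset, "supporting_set"))
  if (is.null(baseline)) baseline <- baseline_scores(sset, m, g)
  qprime <- apply_variant(query, v)
  cluster_means <- vapply(seq_along(sset$clusters), function(c) {
    cl <- sset$clusters[[c]]
    deltas <- vapply(seq_along(cl$members), function(i)
      as.numeric(semiglobal_score(qprime, cl$members[[i]], m, g)) -
        baseline[[c]][i], 0)
    mean(deltas)
  }, 0)
  score <- mean(cluster_means)
  structure(list(variant = v,
                 score = score,
                 cluster_means = cluster_means,
                 n_clusters = n_clusters(sset),
                 n_sequences = n_supporting_sequences(sset),
                 prediction = classify(score, threshold),
                 threshold = threshold),
            class = "provean_result")
}

#' @export
print.provean_result <- function(x, ...) {
  cat(sprintf("<provean_result> %s: score %.3f -> %s (%d cluster(s), %d seq(s))\n",
              format_variant(x$variant), x$score, x$prediction,
              x$n_clusters, x$n_sequences))
  invisible(x)
}

#' Score a batch of variants
#'
#' Driver over [provean_score()]: parses variant strings where needed,
#' computes the reference alignments `S(Q, subject)` once, scores every
#' variant against them, and returns a result table. With
#' `verbose = TRUE` the supporting-set size is logged, a useful diagnostic
#' because accuracy degrades when few supporting sequences are available.
#'
#' @inheritParams provean_score
#' @param variants Character vector of variant strings, or a list of
#'   `protein_variant` objects / records with a `$variant` field.
#' @param verbose Log supporting-set diagnostics via `message()`.
#' @return A data.frame with columns `variant_string`, `provean_score`
#'   (3 decimals), `prediction`, `n_clusters`, `n_supporting_sequences`,
#'   plus a `"results"` attribute holding the full `provean_result` list.
#' @export
provean <- function(query, variants, sset, m = blosum62(),
                    g = gap_penalties(), threshold = -2.282,
                    verbose = FALSE) {
  query <- as_protein_seq(query)
  vs <- lapply(variants, function(v) {
    if (inherits(v, "protein_variant")) v
    else if (is.list(v) && !is.null(v$variant)) v$variant
    else parse_variant(v, query)
  })
  if (verbose)
    message(sprintf("query=%s supporting_sequences=%d clusters=%d",
                    query$id, n_supporting_sequences(sset), n_clusters(sset)))
  baseline <- baseline_scores(sset, m, g)
  results <- lapply(vs, function(v)
    provean_score(query, v, sset, m, g, threshold, baseline = baseline))
  df <- data.frame(
    variant_string = vapply(vs, format_variant, "", query = query),
    provean_score = round(vapply(results, function(r) r$score, 0), 3),
    prediction = vapply(results, function(r) r$prediction, ""),
    n_clusters = vapply(results, function(r) r$n_clusters, 0L),
    n_supporting_sequences = vapply(results, function(r) r$n_sequences, 0L),
    stringsAsFactors = FALSE)
  attr(df, "results") <- results
  df
}

#' @rdname provean
#' @param df Result table from `provean()`.
#' @param path Output TSV path.
#' @param clusters Also write per-cluster means as extra columns.
#' @export
write_provean_tsv <- function(df, path, clusters = FALSE) {
  out <- df
  if (clusters) {
    results <- attr(df, "results")
    if (is.null(results)) stop("result table lacks per-cluster details")
    cm <- lapply(results, function(r) r$cluster_means)
    width <- max(lengths(cm))
    for (k in seq_len(width))
      out[[paste0("cluster_mean_", k)]] <-
        round(vapply(cm, function(x) if (k <= length(x)) x[k] else NA_real_,
                     0), 3)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Saturation scan over all single-residue variants
#'
#' Scores every possible single amino acid substitution (including the
#' identity self-substitution, which is exactly 0), the single-residue
#' deletion, and all 20 single-residue insertions (inserted after the
#' position) at every query position: a length-by-41 matrix mapping the
#' mutational landscape of the protein. Reference alignments are computed
#' once per supporting sequence and reused for every variant; results are
#' identical to independent [provean_score()] calls.
#'
#' @inheritParams provean_score
#' @return Numeric matrix, rows `"<pos><ref>"`, columns `sub_A..sub_V`,
#'   `del`, `ins_A..ins_V`.
#' @export
saturation_scan <- function(query, sset, m = blosum62(), g = gap_penalties()) {
  query <- as_protein_seq(query)
  L <- seq_length(query)
  baseline <- baseline_scores(sset, m, g)
  aas <- AA_STANDARD
  cols <- c(paste0("sub_", aas), "del", paste0("ins_", aas))
  out <- matrix(NA_real_, nrow = L, ncol = length(cols),
                dimnames = list(paste0(seq_len(L), seq_chars(query)), cols))
  score_v <- function(v)
    provean_score(query, v, sset, m, g, baseline = baseline)$score
  for (p in seq_len(L)) {
    ref <- substr(query$residues, p, p)
    for (a in aas) {
      out[p, paste0("sub_", a)] <-
        if (a == ref) 0 else score_v(variant("substitution", p, ref, a))
      out[p, paste0("ins_", a)] <- score_v(variant("insertion", p, "", a))
    }
    out[p, "del"] <- if (L > 1L) score_v(variant("deletion", p, ref, "")) else
      NA_real_
  }
  out
}

#' @rdname saturation_scan
#' @param mat Matrix from `saturation_scan()`.
#' @param path Output TSV path.
#' @export
write_scan_tsv <- function(mat, path) {
  df <- data.frame(position = rownames(mat), round(mat, 3),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
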