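#' Labeled score sets
#'
#' Evaluation utilities operate on a data.frame with columns `score`
#' (numeric) and `label` (`"deleterious"` / `"neutral"`); deleterious is
#' the positive class, and lower scores are more deleterious.
#'
#' @param score Numeric scores.
#' @param label Character labels.
#' @return A validated data.frame.
#' @export
labeled_scores <- function(score, label) {
  stopifnot(length(score) == length(label), all(is.finite(score)))
  bad <- setdiff(unique(label), c("deleterious", "neutral"))
  if (length(bad))
    stop("labels must be 'deleterious' or 'neutral'; found: ",
         paste(bad, collapse = ", "))
  data.frame(score = as.numeric(score), label = as.character(label),
             stringsAsFactors = FALSE)
}

check_both_classes <- function(df) {
  if (!all(c("deleterious", "neutral") %in% df$label))
    stop("both classes must be present; sensitivity/specificity undefined ",
         "on a single-class input")
  invisible(df)
}

#' Balanced accuracy
#'
#' The simple average of sensitivity and specificity,
#' `(sensitivity + specificity) / 2`, on the percent scale. Used instead of
#' raw accuracy so that class imbalance does not distort threshold
#' selection or performance measurement.
#'
#' @param sensitivity,specificity Percentages in `[0, 100]`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' balanced_accuracy(78.39, 79.11)  # 78.75
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Confusion metrics at a threshold
#'
#' Applies the deleterious-iff-`score <= threshold` rule and reports the
#' confusion counts, sensitivity (deleterious detection rate), specificity
#' (neutral retention rate), and [balanced_accuracy()], all on the percent
#' scale.
#'
#' @param df A [labeled_scores()] data.frame.
#' @param threshold Decision threshold.
#' @return An object of class `eval_report`: list with `threshold`, `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
confusion <- function(df, threshold) {
  df <- check_both_classes(labeled_scores(df$score, df$label))
  pos <- df$label == "deleterious"
  called <- df$score <= threshold
  tp <- sum(pos & called); fn <- sum(pos & !called)
  tn <- sum(!pos & !called); fp <- sum(!pos & called)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = balanced_accuracy(sens, spec)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> threshold %.3f: sens %.2f%%, spec ",
                     "%.2f%%, balanced acc %.2f%% (TP %d FP %d TN %d FN %d)\n"),
              x$threshold, x$sensitivity, x$specificity,
              x$balanced_accuracy, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# candidate cutoffs: midpoints between adjacent distinct scores, plus
# sentinels below/above every score
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
}

#' Balanced-separation threshold selection
#'
#' Scans candidate thresholds (midpoints between adjacent distinct scores,
#' plus one candidate below and one above all scores) and returns the one
#' that maximizes the minimum of sensitivity and specificity. Ties in that
#' objective are broken by higher balanced accuracy, then by the largest
#' threshold, making the result deterministic.
#'
#' @param df A [labeled_scores()] data.frame.
#' @return The selected threshold (numeric scalar), with the achieved
#'   objective in attribute `"objective"`.
#' @export
select_threshold <- function(df) {
  df <- check_both_classes(labeled_scores(df$score, df$label))
  cand <- threshold_candidates(df$score)
  best <- NULL
  for (t in cand) {
    r <- confusion(df, t)
    key <- c(min(r$sensitivity, r$specificity), r$balanced_accuracy, t)
    if (is.null(best) || lex_greater(key, best$key))
      best <- list(key = key, threshold = t)
  }
  structure(best$threshold, objective = best$key[1])
}

lex_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' ROC area under the curve
#'
#' AUC with deleterious ranked by lower score: the probability that a
#' randomly chosen deleterious variant scores below a randomly chosen
#' neutral one, ties counted half (the normalized Mann-Whitney U
#' statistic). Computed from ranks, so it is invariant under any strictly
#' monotone transformation of the scores.
#'
#' @param df A [labeled_scores()] data.frame.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(df) {
  df <- check_both_classes(labeled_scores(df$score, df$label))
  pos <- df$label == "deleterious"
  r <- rank(df$score) # average ranks: ties counted half
  n_d <- sum(pos); n_n <- sum(!pos)
  u_above <- sum(r[pos]) - n_d * (n_d + 1) / 2 # pairs where d > n (+ half ties)
  1 - u_above / (n_d * n_n)
}

#' @rdname roc_auc
#' @return `roc_points()` returns a data.frame of (fpr, tpr) pairs over all
#'   candidate thresholds, suitable for plotting or CSV export.
#' @export
roc_points <- function(df) {
  df <- check_both_classes(labeled_scores(df$score, df$label))
  pts <- t(vapply(threshold_candidates(df$score), function(t) {
    r <- confusion(df, t)
    c(fpr = 100 - r$specificity, tpr = r$sensitivity)
  }, c(fpr = 0, tpr = 0)))
  as.data.frame(pts[order(pts[, "fpr"], pts[, "tpr"]), ])
}

#' Parameter grid enumeration
#'
#' Expands the three tuning axes of the scoring pipeline - gap penalty
#' pairs, clustering identity thresholds, and supporting-set cluster-count
#' caps - into one row per combination. The default axes span 6 gap pairs,
#' 7 identities and 18 cluster counts (756 combinations), the scale at
#' which the default parameters (10/1, 80%, 45) were originally selected.
#'
#' @param gap_penalty_pairs List of `c(open, extend)` pairs.
#' @param identity_thresholds Numeric identities in `(0, 1]`.
#' @param cluster_counts Integer cluster caps.
#' @return A data.frame with columns `gap_open`, `gap_extend`, `identity`,
#'   `max_clusters`.
#' @examples
#' nrow(sweep_grid())  # 756
#' @export
sweep_grid <- function(gap_penalty_pairs = default_gap_pairs(),
                       identity_thresholds = seq(0.65, 0.95, by = 0.05),
                       cluster_counts = seq(5L, 90L, by = 5L)) {
  stopifnot(length(gap_penalty_pairs) > 0, length(identity_thresholds) > 0,
            length(cluster_counts) > 0)
  gp <- do.call(rbind, lapply(gap_penalty_pairs, function(p) {
    stopifnot(length(p) == 2)
    data.frame(gap_open = p[1], gap_extend = p[2])
  }))
  grid <- expand.grid(pair = seq_len(nrow(gp)),
                      identity = identity_thresholds,
                      max_clusters = as.integer(cluster_counts),
                      KEEP.OUT.ATTRS = FALSE)
  out <- cbind(gp[grid$pair, , drop = FALSE],
               grid[c("identity", "max_clusters")])
  rownames(out) <- NULL
  out
}

#' @rdname sweep_grid
#' @export
default_gap_pairs <- function() {
  list(c(8, 1), c(8, 2), c(10, 1), c(10, 2), c(12, 2), c(12, 3))
}

#' Parameter-grid sweep
#'
#' Re-scores a labeled variant set under every parameter combination of a
#' [sweep_grid()] and reports, per combination, the balanced-separation
#' threshold ([select_threshold()]) and the balanced accuracy achieved at
#' it. The supporting set is rebuilt for each (identity, cluster-cap) pair
#' and the variants re-scored with that cell's gap penalties, so the sweep
#' is exact but costly: grid size times the cost of one full scoring pass.
#' Cells are independent, and the output is identical to serial execution.
#'
#' @inheritParams provean
#' @param records Labeled variant records (`list(variant, label)`), e.g.
#'   from [read_variant_tsv()] or [generate_labeled_variants()]; labels
#'   must include both classes.
#' @param homologs List of candidate supporting [protein_seq].
#' @param grid A [sweep_grid()] data.frame.
#' @param m A [subst_matrix].
#' @return `grid` with added columns `threshold` and `balanced_accuracy`.
#' @export
parameter_sweep <- function(query, records, homologs, grid = sweep_grid(),
                            m = blosum62()) {
  query <- as_protein_seq(query)
  labels <- vapply(records, function(r) r$label, "")
  grid$threshold <- NA_real_
  grid$balanced_accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    g <- gap_penalties(grid$gap_open[i], grid$gap_extend[i])
    sset <- build_supporting_set(query, homologs,
                                 identity_threshold = grid$identity[i],
                                 max_clusters = grid$max_clusters[i],
                                 m = m, g = g)
    res <- provean(query, records, sset, m = m, g = g)
    ls <- labeled_scores(res$provean_score, labels)
    thr <- select_threshold(ls)
    grid$threshold[i] <- as.numeric(thr)
    grid$balanced_accuracy[i] <- confusion(ls, thr)$balanced_accuracy
  }
  grid
}

#' Read and summarize variant count tables
#'
#' `read_count_table()` reads a TSV whose first column names a category and
#' whose remaining columns are non-negative counts; `count_totals()` sums
#' each numeric column. Two reference count tables ship with the package
#' under `inst/extdata/`: `uniprot_human_variant_counts.tsv` (published
#' deleterious/neutral counts per variation class of a curated human
#' variant set) and `indel_validation_counts.tsv` (published indel counts
#' by length from a disease-mutation database and a population-variation
#' catalogue).
#'
#' @param path TSV path.
#' @return `read_count_table()`: a data.frame; `count_totals()`: named
#'   numeric vector of column sums.
#' @export
read_count_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_count_table
#' @param df Data frame of counts.
#' @export
count_totals <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  colSums(df[num])
}

#' @rdname labeled_scores
#' @param path TSV path with columns `score` and `label`.
#' @export
read_labeled_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  labeled_scores(df$score, df$label)
}

#' @rdname labeled_scores
#' @param df A labeled-scores data.frame.
#' @export
write_labeled_scores <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
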