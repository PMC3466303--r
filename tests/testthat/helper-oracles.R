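# Independent oracles used across the suite. They share no code with the
# package's alignment/evaluation paths: alignment is checked by exhaustive
# enumeration of alignment paths, threshold selection and AUC by naive
# all-candidate / all-pairs loops, clustering by a straightforward
# re-implementation of the greedy rule.

.path_cache <- new.env(parent = emptyenv())

# all monotone lattice paths (move alphabet U = consume a, L = consume b,
# D = consume both) from (0,0) to (m,n), cached by shape
enum_paths <- function(m, n) {
  key <- paste(m, n, sep = "_")
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  res <- if (m == 0 && n == 0) {
    list(character(0))
  } else {
    out <- list()
    if (m > 0)
      out <- c(out, lapply(enum_paths(m - 1, n), function(p) c(p, "U")))
    if (n > 0)
      out <- c(out, lapply(enum_paths(m, n - 1), function(p) c(p, "L")))
    if (m > 0 && n > 0)
      out <- c(out, lapply(enum_paths(m - 1, n - 1), function(p) c(p, "D")))
    out
  }
  .path_cache[[key]] <- res
  res
}

# exhaustive semi-global alignment: maximum score over every alignment path,
# charging affine costs for every internal gap run; the first and last runs
# of the path, if gap runs, are end gaps and free. Returns the score and the
# maximum identity count among score-optimal paths.
oracle_semiglobal <- function(a, b, m = blosum62(), g = gap_penalties()) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  S <- m$scores
  gfirst <- if (g$convention == "first_residue_costs_open_only") g$open
            else g$open + g$extend
  best <- -Inf; best_id <- -1L
  for (p in enum_paths(length(A), length(B))) {
    i <- cumsum(p != "L"); j <- cumsum(p != "U")
    d <- p == "D"
    sc <- sum(S[cbind(A[i[d]], B[j[d]])])
    idc <- sum(A[i[d]] == B[j[d]])
    r <- rle(p)
    nr <- length(r$lengths)
    for (k in seq_len(nr)) {
      if (r$values[k] == "D" || k == 1L || k == nr) next
      sc <- sc - (gfirst + (r$lengths[k] - 1L) * g$extend)
    }
    if (sc > best) { best <- sc; best_id <- idc }
    else if (sc == best && idc > best_id) best_id <- idc
  }
  list(score = best, identities = best_id)
}

# best ungapped overlap placement: slide b along a, sum matched-pair scores
oracle_ungapped_overlap <- function(a, b, m = blosum62()) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  S <- m$scores
  best <- -Inf
  for (off in seq(-(length(B) - 1L), length(A) - 1L)) {
    i <- intersect(seq_along(A), seq_along(B) + off)
    if (!length(i)) next
    best <- max(best, sum(S[cbind(A[i], B[i - off])]))
  }
  best
}

# independent greedy clustering: same stated rule, separate implementation;
# returns the partition as a list of integer index vectors into `seqs`
oracle_greedy_partition <- function(seqs, threshold,
                                    identity_fun = pairwise_identity) {
  lens <- vapply(seqs, seq_length, 0L)
  res <- vapply(seqs, function(s) s$residues, "")
  ids <- vapply(seqs, function(s) s$id, "")
  ord <- order(-lens, res, ids)
  reps <- integer(0)
  part <- list()
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (identity_fun(seqs[[i]], seqs[[reps[k]]]) >= threshold) {
        hit <- k; break
      }
    }
    if (hit > 0L) part[[hit]] <- c(part[[hit]], i)
    else { reps <- c(reps, i); part[[length(part) + 1L]] <- i }
  }
  part
}

# brute-force balanced-separation maximizer over all cut points
oracle_select_threshold <- function(score, label) {
  s <- sort(unique(score))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best_obj <- -Inf
  for (t in cand) {
    tp <- sum(label == "deleterious" & score <= t)
    fn <- sum(label == "deleterious" & score > t)
    tn <- sum(label == "neutral" & score > t)
    fp <- sum(label == "neutral" & score <= t)
    obj <- min(100 * tp / (tp + fn), 100 * tn / (tn + fp))
    best_obj <- max(best_obj, obj)
  }
  best_obj
}

# all-pairs Mann-Whitney AUC: wins + half-ties, deleterious lower
oracle_auc <- function(score, label) {
  d <- score[label == "deleterious"]
  n <- score[label == "neutral"]
  total <- 0
  for (x in d) for (y in n)
    total <- total + (x < y) + 0.5 * (x == y)
  total / (length(d) * length(n))
}

random_protein <- function(len, alphabet = AA_STANDARD, id = "r") {
  protein_seq(paste(sample(alphabet, len, replace = TRUE), collapse = ""),
              id = id)
}

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")
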