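# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Synthetic homolog-family model
#'
#' Describes a simulated protein family with the statistical structure the
#' delta-score method exploits: a set of conserved positions that never
#' vary across homologs (standing in for functionally constrained sites)
#' and free positions that accumulate substitutions and small indels.
#' Homologs are organized into subfamilies (an ancestor per subfamily,
#' leaves mutated from it) so that identity clustering has real structure
#' to find and the equal-cluster-weight average is exercised against
#' overrepresented subfamilies. Generation is a pure function of `seed`.
#'
#' Defaults: a 120-residue protein with one third of positions conserved,
#' free-position substitution rate 0.4, indel rate 0.02 per free position,
#' 60 homologs in 5 subfamilies - a small but realistic desk-scale family
#' (real supporting sets typically hold 100-200 sequences).
#'
#' @param length Protein length (>= 2).
#' @param conserved_positions Integer positions held invariant; `NULL`
#'   samples `round(length / 3)` positions deterministically from `seed`.
#' @param substitution_rate_free Per-position substitution probability at
#'   free positions (mutated residues are drawn uniformly from the 19
#'   alternatives).
#' @param indel_rate Per-free-position probability of a small indel in a
#'   leaf homolog (split evenly between a single-residue deletion and a
#'   geometric-length insertion, mean 2).
#' @param n_homologs Number of homologs to generate (> 0).
#' @param n_subfamilies Number of subfamilies; subfamily 1's ancestor is
#'   the query itself.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `family_model`. The field `indel_segments`
#'   (derived deterministically from the seed) lists short free-sequence
#'   segments treated as indel-tolerant: their presence varies across
#'   homologs, emulating loop-length polymorphism, and neutral indel
#'   variants are anchored there.
#' @export
family_model <- function(length = 120L, conserved_positions = NULL,
                         substitution_rate_free = 0.4, indel_rate = 0.02,
                         n_homologs = 60L, n_subfamilies = 5L, seed = 1L) {
  length <- as.integer(length)
  if (is.na(length) || length < 2L) stop("degenerate model: length < 2")
  if (n_homologs < 1L) stop("degenerate model: n_homologs < 1")
  stopifnot(n_subfamilies >= 1L,
            substitution_rate_free >= 0, substitution_rate_free <= 1,
            indel_rate >= 0, indel_rate <= 1)
  if (is.null(conserved_positions)) {
    conserved_positions <- with_seed(seed + 1L,
      sort(sample.int(length, max(1L, round(length / 3)))))
  }
  conserved_positions <- sort(unique(as.integer(conserved_positions)))
  stopifnot(all(conserved_positions >= 1L), all(conserved_positions <= length))
  model <- structure(
    list(length = length,
         conserved_positions = conserved_positions,
         substitution_rate_free = substitution_rate_free,
         indel_rate = indel_rate,
         n_homologs = as.integer(n_homologs),
         n_subfamilies = as.integer(n_subfamilies),
         seed = as.integer(seed)),
    class = "family_model")
  model$indel_segments <- pick_indel_segments(model)
  model
}

# indel-tolerant segments: short stretches of free sequence whose presence
# varies across homologs, emulating loop-length polymorphism. Real families
# tolerate indels only in such regions; without them every indel - neutral
# or not - pays a full gap penalty against every homolog and the generator
# would mislabel indels it calls neutral. Chosen deterministically from the
# model seed: about one segment per 40 residues, length 2-4, wholly inside
# runs of free positions.
pick_indel_segments <- function(model) {
  free <- setdiff(seq_len(model$length), model$conserved_positions)
  if (!length(free)) return(list())
  r <- rle(seq_len(model$length) %in% free)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  cand <- which(r$values & r$lengths >= 2L)
  if (!length(cand)) return(list())
  with_seed(model$seed + 2L, {
    n_seg <- min(length(cand), max(1L, round(model$length / 40)))
    runs <- cand[sample.int(length(cand), n_seg)]
    lapply(runs, function(k) {
      len <- min(r$lengths[k], sample(2:4, 1L))
      start <- run_start[k] +
        sample.int(r$lengths[k] - len + 1L, 1L) - 1L
      seq.int(start, start + len - 1L)
    })
  })
}

#' @export
print.family_model <- function(x, ...) {
  cat(sprintf(paste0("<family_model> %d aa (%d conserved), %d homolog(s) in ",
                     "%d subfamilies, sub rate %.2f, indel rate %.3f, seed %d\n"),
              x$length, length(x$conserved_positions), x$n_homologs,
              x$n_subfamilies, x$substitution_rate_free, x$indel_rate,
              x$seed))
  invisible(x)
}

# substitute free positions of a residue vector at the given rate;
# replacements drawn uniformly from the 19 alternatives
mutate_free <- function(chars, free_mask, rate) {
  hit <- free_mask & (stats::runif(length(chars)) < rate)
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
  }
  chars
}

#' Generate a synthetic homolog family
#'
#' Draws a query uniformly over the 20 standard amino acids, then derives
#' homologs subfamily by subfamily: each subfamily has an ancestor
#' (subfamily 1's ancestor is the query; the others are the query mutated
#' at free positions), and each leaf homolog mutates its ancestor again at
#' free positions and may gain small indels at free positions. Conserved
#' positions are never substituted or deleted, and insertions never land
#' immediately after a position that precedes a conserved one, so the
#' conserved residues are present, in order, in every homolog (with
#' `indel_rate = 0` they sit at identical column positions).
#'
#' @param model A [family_model()].
#' @return `list(query = protein_seq, homologs = list of protein_seq)`.
#' @examples
#' fam <- generate_family(family_model(length = 40, n_homologs = 5, seed = 7))
#' fam$query
#' @export
generate_family <- function(model) {
  stopifnot(inherits(model, "family_model"))
  with_seed(model$seed, {
    L <- model$length
    free_mask <- !(seq_len(L) %in% model$conserved_positions)
    qchars <- sample(AA_STANDARD, L, replace = TRUE)
    ancestors <- vector("list", model$n_subfamilies)
    ancestors[[1]] <- qchars
    for (s in seq_len(model$n_subfamilies)[-1])
      ancestors[[s]] <- mutate_free(qchars, free_mask,
                                    model$substitution_rate_free)
    subfam <- rep_len(seq_len(model$n_subfamilies), model$n_homologs)
    homologs <- vector("list", model$n_homologs)
    for (h in seq_len(model$n_homologs)) {
      chars <- mutate_free(ancestors[[subfam[h]]], free_mask,
                           model$substitution_rate_free)
      if (model$indel_rate > 0) {
        pieces <- as.list(chars)
        # length polymorphism in the indel-tolerant segments: whole-segment
        # absence (rate 20x the scattered indel rate, capped) or an
        # insertion just after the segment (10x)
        p_del <- min(0.5, 20 * model$indel_rate)
        p_ins <- min(0.25, 10 * model$indel_rate)
        for (seg in model$indel_segments) {
          u <- stats::runif(1)
          if (u < p_del) {
            for (i in seg) pieces[[i]] <- character(0)
          } else if (u < p_del + p_ins) {
            ins <- sample(AA_STANDARD, sample(1:3, 1L), replace = TRUE)
            last <- seg[length(seg)]
            pieces[[last]] <- c(pieces[[last]], ins)
          }
        }
        # rare scattered single-residue indels anywhere in free sequence
        for (i in which(free_mask)) {
          if (stats::runif(1) < model$indel_rate) {
            if (stats::runif(1) < 0.5) {
              pieces[[i]] <- character(0) # delete the free residue
            } else {
              ins <- sample(AA_STANDARD, 1L + stats::rgeom(1L, 0.5),
                            replace = TRUE)
              pieces[[i]] <- c(pieces[[i]], ins)
            }
          }
        }
        chars <- unlist(pieces)
        if (!length(chars)) chars <- qchars # pathological all-deleted case
      }
      homologs[[h]] <- protein_seq(paste(chars, collapse = ""),
                                   id = sprintf("hom%03d_sf%d", h, subfam[h]))
    }
    list(query = protein_seq(paste(qchars, collapse = ""), id = "query"),
         homologs = homologs)
  })
}

# contiguous runs of positions from a logical mask, as a list of windows
mask_runs <- function(mask, len) {
  out <- list()
  pos <- which(mask)
  if (!length(pos)) return(out)
  for (p in pos) {
    if (p + len - 1L <= length(mask) && all(mask[p:(p + len - 1L)]))
      out[[length(out) + 1L]] <- p
  }
  unlist(out)
}

#' Generate labeled variants for a synthetic family
#'
#' Builds a labeled benchmark set against the family's query: "deleterious"
#' variants hit conserved positions (substitutions, deletions, insertions
#' between conserved neighbors, replacements of conserved runs) and
#' "neutral" variants hit free positions. All four variant classes are
#' drawn (roughly 70% substitutions, 10% each of deletions, insertions,
#' replacements), all with `|ref|, |alt| <= 3`, and every record satisfies
#' the variant invariants against the query.
#'
#' @param model A [family_model()].
#' @param query The family query returned by [generate_family()].
#' @param n_deleterious,n_neutral Number of variants per class.
#' @param seed Seed for variant sampling (defaults to `model$seed + 1000`).
#' @return List of records `list(variant, label)`.
#' @export
generate_labeled_variants <- function(model, query, n_deleterious,
                                      n_neutral,
                                      seed = model$seed + 1000L) {
  stopifnot(inherits(model, "family_model"))
  query <- as_protein_seq(query)
  L <- seq_length(query)
  stopifnot(L == model$length)
  cons_mask <- seq_len(L) %in% model$conserved_positions
  if (n_deleterious + n_neutral == 0) return(list())
  if (!any(cons_mask) || all(cons_mask))
    stop("model needs both conserved and free positions to label variants")
  qchars <- seq_chars(query)
  seg_pos <- sort(unique(unlist(model$indel_segments)))

  # neutral changes mimic surviving polymorphisms: conservative residue
  # swaps (non-negative BLOSUM62 score against the reference); deleterious
  # changes are unconstrained (radical on average)
  blos <- blosum62()$scores
  draw_alt <- function(ref_aa, label) {
    pool <- setdiff(AA_STANDARD, ref_aa)
    if (label == "neutral") {
      cons_pool <- pool[blos[ref_aa, pool] >= 0]
      if (length(cons_pool)) pool <- cons_pool
      else pool <- pool[which.max(blos[ref_aa, pool])]
    }
    sample(rep(pool, 2L), 1L)
  }

  draw_one <- function(label) {
    mask <- if (label == "deleterious") cons_mask else !cons_mask
    # neutral indels go to the indel-tolerant segments when the model has
    # them (elsewhere even a "free" indel costs a gap in every homolog)
    indel_mask <- if (label == "neutral" && length(seg_pos))
      seq_len(L) %in% seg_pos else mask
    kind <- sample(c("substitution", "deletion", "insertion", "replacement"),
                   1L, prob = c(0.7, 0.1, 0.1, 0.1))
    len <- sample(1:3, 1L)
    if (kind == "substitution") {
      p <- sample(rep(which(mask), 2L), 1L)
      return(variant("substitution", p, qchars[p], draw_alt(qchars[p], label)))
    }
    if (kind == "insertion") {
      # deleterious: between two conserved neighbors when possible
      starts <- mask_runs(indel_mask, 2L)
      p <- if (length(starts)) sample(rep(starts, 2L), 1L) else
        sample(rep(which(indel_mask), 2L), 1L)
      return(variant("insertion", p, "",
                     paste(sample(AA_STANDARD, len, replace = TRUE),
                           collapse = "")))
    }
    # deletion / replacement need a fully in-class ref window (not the
    # whole sequence, and at least one residue must survive a deletion)
    wmask <- if (kind == "deletion") indel_mask else mask
    repeat {
      starts <- mask_runs(wmask, len)
      starts <- starts[starts + len - 1L < L | starts > 1L]
      if (length(starts) || len == 1L) break
      len <- len - 1L
    }
    if (!length(starts))
      stop("insufficient ", label, " positions for a length-", len, " ", kind)
    p <- sample(rep(starts, 2L), 1L)
    ref <- paste(qchars[p:(p + len - 1L)], collapse = "")
    if (kind == "deletion") return(variant("deletion", p, ref, ""))
    alt_len <- if (len == 1L) 2L else sample(1:3, 1L)
    alt <- if (label == "neutral")
      paste(vapply(strsplit(ref, "")[[1]][seq_len(min(len, alt_len))],
                   draw_alt, "", label = label), collapse = "")
      else paste(sample(AA_STANDARD, alt_len, replace = TRUE), collapse = "")
    if (!nzchar(alt) || (nchar(ref) == 1L && nchar(alt) == 1L))
      alt <- paste0(alt, draw_alt(qchars[p], label))
    variant("replacement", p, ref, alt)
  }

  with_seed(seed, {
    labels <- c(rep("deleterious", n_deleterious), rep("neutral", n_neutral))
    lapply(labels, function(lab) list(variant = draw_one(lab), label = lab))
  })
}
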