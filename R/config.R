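#' Pipeline configuration
#'
#' One flat configuration object carries every tunable of the scoring
#' pipeline; [provean_config()] returns the defaults, optionally overridden
#' by named arguments, and [read_provean_config()] merges overrides from a
#' JSON file (keys as below). Defaults are the selected operating point of
#' the method: BLOSUM62, gap open 10 / extend 1 (classic affine
#' convention), 80% clustering identity, 45-cluster cap, decision threshold
#' -2.282.
#'
#' @param ... Named overrides of the fields `matrix` (path to an
#'   NCBI-format matrix file, or `"BLOSUM62"` for the bundled one),
#'   `gap_open`, `gap_extend`, `gap_convention`, `identity_threshold`,
#'   `max_clusters`, `threshold`, `e_threshold`, `seed`.
#' @return A list of class `provean_config`.
#' @export
provean_config <- function(...) {
  cfg <- list(matrix = "BLOSUM62",
              gap_open = 10L,
              gap_extend = 1L,
              gap_convention = "first_residue_costs_open_only",
              identity_threshold = 0.80,
              max_clusters = 45L,
              threshold = -2.282,
              e_threshold = 0.1,
              seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "provean_config")
}

#' @rdname provean_config
#' @param path JSON file of overrides.
#' @export
read_provean_config <- function(path) {
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(provean_config, as.list(over))
}

config_matrix <- function(cfg) {
  if (identical(cfg$matrix, "BLOSUM62")) blosum62()
  else read_subst_matrix(cfg$matrix)
}

config_gaps <- function(cfg) {
  gap_penalties(cfg$gap_open, cfg$gap_extend, cfg$gap_convention)
}
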