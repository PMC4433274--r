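# Seed extraction and cross-species conservation classification: a
# candidate is conserved relative to a panel miRNA when the seeds
# (mature positions 2-8 by default) are identical and at least half of
# the overall mature sequence matches.

#' Extract the seed from a mature miRNA sequence
#'
#' The seed is the 1-based inclusive slice `[seed_start, seed_end]` of
#' the mature sequence (default positions 2-8, a 7-mer).
#'
#' @param mature RNA string, length at least `seed_end`.
#' @param config A [pipeline_config()].
#' @return The seed as an RNA string.
#' @export
#' @examples
#' extract_seed("UAGCUUAUCAGACUGAUGUUGA")  # "AGCUUAU"
extract_seed <- function(mature, config = pipeline_config()) {
  mature <- normalize_rna(mature)
  if (any(nchar(mature) < config$seed_end)) {
    stop("validation error: mature sequence shorter than seed_end",
         call. = FALSE)
  }
  substr(mature, config$seed_start, config$seed_end)
}

# Longest common subsequence length: the maximum number of identical
# aligned nucleotides under a global alignment scoring match +1,
# mismatch 0, gap 0.
lcs_length <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (x[i] == y[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Overall identity between two mature sequences
#'
#' Maximizes the number of identical aligned nucleotides (global
#' alignment, match +1, mismatch 0, gaps free) and reports it as a
#' percentage of the longer sequence by default (conservative), the
#' shorter, or the alignment length.
#'
#' @param a,b RNA strings (non-empty).
#' @param denominator `"longer"` (default), `"shorter"` or
#'   `"alignment"`.
#' @return Identity percentage, rounded half-up to 2 decimals.
#' @export
#' @examples
#' overall_identity("AAAA", "AAAU")  # 75
overall_identity <- function(a, b,
                             denominator = c("longer", "shorter",
                                             "alignment")) {
  denominator <- match.arg(denominator)
  a <- normalize_rna(a); b <- normalize_rna(b)
  matches <- lcs_length(a, b)
  den <- switch(denominator,
                longer = max(nchar(a), nchar(b)),
                shorter = min(nchar(a), nchar(b)),
                alignment = nchar(a) + nchar(b) - matches)
  percent(matches, den)
}

#' Classify conservation of novel candidates against a known panel
#'
#' Every candidate x panel pair is scored: `seed_exact` is exact string
#' equality of the seeds, `overall_identity` the maximal-match identity
#' percentage, and `conserved` requires both an exact seed and identity
#' of at least `identity_threshold * 100`. Seed comparison tolerates no
#' G:U wobble. Output is sorted by candidate then descending identity;
#' the `species` column supports the same-species (seed family)
#' reading directly.
#'
#' @param candidates Data frame with `candidate_id` and
#'   `mature_sequence` (e.g. from [discover_candidates()]).
#' @param panel Annotation data frame (non-empty).
#' @param config A [pipeline_config()].
#' @return Data frame with columns `candidate_id`, `known_name`,
#'   `species`, `overall_identity`, `seed_exact`, `conserved`.
#' @export
classify_conservation <- function(candidates, panel,
                                  config = pipeline_config()) {
  if (nrow(panel) == 0L) {
    stop("validation error: panel must be non-empty", call. = FALSE)
  }
  out <- data.frame(candidate_id = character(0), known_name = character(0),
                    species = character(0), overall_identity = numeric(0),
                    seed_exact = logical(0), conserved = logical(0),
                    stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(out)
  cand_seed <- extract_seed(candidates$mature_sequence, config)
  panel_seed <- extract_seed(panel$mature_sequence, config)
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ident <- vapply(panel$mature_sequence, function(p) {
      overall_identity(candidates$mature_sequence[i], p,
                       denominator = config$identity_denominator)
    }, numeric(1), USE.NAMES = FALSE)
    seed_exact <- cand_seed[i] == panel_seed
    df <- data.frame(
      candidate_id = candidates$candidate_id[i],
      known_name = panel$name, species = panel$species,
      overall_identity = ident, seed_exact = seed_exact,
      conserved = seed_exact & ident >= config$identity_threshold * 100,
      stringsAsFactors = FALSE)
    rows[[i]] <- df[order(-df$overall_identity, df$known_name), ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mf_log("classify_conservation: %d candidates vs %d panel entries, %d conserved pairs",
         nrow(candidates), nrow(panel), sum(out$conserved))
  out
}

#' Summarize seed families per candidate
#'
#' Counts, per candidate, the panel members sharing its exact seed —
#' overall and restricted to a reference species (human by default) —
#' the basis for grouping candidates into miRNA families.
#'
#' @param hits Output of [classify_conservation()].
#' @param same_species Species code for the same-species tally
#'   (default `"hsa"`).
#' @return Data frame with `candidate_id`, `n_seed_shared`,
#'   `n_seed_shared_same_species`, `n_conserved`.
#' @export
seed_family_summary <- function(hits, same_species = "hsa") {
  ids <- unique(hits$candidate_id)
  data.frame(
    candidate_id = ids,
    n_seed_shared = vapply(ids, function(id)
      sum(hits$seed_exact[hits$candidate_id == id]), integer(1),
      USE.NAMES = FALSE),
    n_seed_shared_same_species = vapply(ids, function(id)
      sum(hits$seed_exact[hits$candidate_id == id &
                          hits$species == same_species]), integer(1),
      USE.NAMES = FALSE),
    n_conserved = vapply(ids, function(id)
      sum(hits$conserved[hits$candidate_id == id]), integer(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}
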