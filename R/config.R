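#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the study
#' defaults: reads shorter than 18 nt are low quality, novel candidates
#' need at least 10 supporting reads, differential expression requires
#' p < 0.05 and a fold change strictly above 2.0 (or below 0.5),
#' conservation requires an exact seed (mature positions 2-8, 1-based
#' inclusive) plus at least 50% overall identity, pathway relatedness
#' requires seed sites in at least 2 distinct pathway genes, and loci
#' within 10 kb are clustered.
#'
#' @param min_read_length Minimum read length in nt counted as high
#'   quality (default 18).
#' @param min_candidate_count Minimum total read count for a retained
#'   novel candidate (default 10).
#' @param p_threshold Two-sided p-value threshold (default 0.05).
#' @param fold_threshold Fold-change gate, strict (default 2.0).
#' @param identity_threshold Minimum overall identity fraction for
#'   conservation (default 0.50).
#' @param seed_start,seed_end 1-based inclusive seed positions in the
#'   mature sequence (defaults 2 and 8).
#' @param min_pathway_targets Minimum distinct pathway genes targeted for
#'   pathway relatedness (default 2).
#' @param cluster_gap Maximum end-to-start gap in bases joining loci into
#'   a genomic cluster (default 10000).
#' @param rng_seed Integer seed for any randomized step (default 1).
#' @param min_loop Minimum hairpin loop length in nt for folding
#'   (default 3, the sterically minimal loop).
#' @param min_mature_paired Minimum fraction of mature bases paired in
#'   the precursor fold (default 0.6).
#' @param min_helix_stack Minimum stacked pairs for a helix to count
#'   toward the single-stem topology test (default 3).
#' @param precursor_upstream,precursor_downstream Precursor excision
#'   window around the mature locus, in nt (defaults 20 and 50; the
#'   mirrored window is also tried).
#' @param locus_merge_gap Maximum nt between genome hits grouped into one
#'   candidate locus (default 30).
#' @param pseudocount Added to normalized values before testing
#'   (default 0; only needed with `log2_transform`).
#' @param log2_transform Test log2-transformed normalized values instead
#'   of plain reads-per-million (default FALSE).
#' @param identity_denominator Denominator for overall identity: length of
#'   the `"longer"` sequence (default), the `"shorter"`, or the
#'   `"alignment"` (longer + shorter - matches).
#' @return An object of class `pipeline_config` (a validated list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$fold_threshold
pipeline_config <- function(min_read_length = 18L,
                            min_candidate_count = 10L,
                            p_threshold = 0.05,
                            fold_threshold = 2.0,
                            identity_threshold = 0.50,
                            seed_start = 2L,
                            seed_end = 8L,
                            min_pathway_targets = 2L,
                            cluster_gap = 10000L,
                            rng_seed = 1L,
                            min_loop = 3L,
                            min_mature_paired = 0.6,
                            min_helix_stack = 3L,
                            precursor_upstream = 20L,
                            precursor_downstream = 50L,
                            locus_merge_gap = 30L,
                            pseudocount = 0,
                            log2_transform = FALSE,
                            identity_denominator = c("longer", "shorter",
                                                     "alignment")) {
  cfg <- list(
    min_read_length = as.integer(min_read_length),
    min_candidate_count = as.integer(min_candidate_count),
    p_threshold = p_threshold,
    fold_threshold = fold_threshold,
    identity_threshold = identity_threshold,
    seed_start = as.integer(seed_start),
    seed_end = as.integer(seed_end),
    min_pathway_targets = as.integer(min_pathway_targets),
    cluster_gap = as.integer(cluster_gap),
    rng_seed = as.integer(rng_seed),
    min_loop = as.integer(min_loop),
    min_mature_paired = min_mature_paired,
    min_helix_stack = as.integer(min_helix_stack),
    precursor_upstream = as.integer(precursor_upstream),
    precursor_downstream = as.integer(precursor_downstream),
    locus_merge_gap = as.integer(locus_merge_gap),
    pseudocount = pseudocount,
    log2_transform = isTRUE(log2_transform),
    identity_denominator = match.arg(identity_denominator)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, why) {
    if (!ok) stop(sprintf("configuration error: %s %s", key, why),
                  call. = FALSE)
  }
  chk(cfg$min_read_length >= 1, "min_read_length", "must be >= 1")
  chk(cfg$min_candidate_count >= 1, "min_candidate_count", "must be >= 1")
  chk(cfg$p_threshold > 0 && cfg$p_threshold < 1, "p_threshold",
      "must lie in (0, 1)")
  chk(cfg$fold_threshold > 1, "fold_threshold", "must be > 1")
  chk(cfg$identity_threshold > 0 && cfg$identity_threshold <= 1,
      "identity_threshold", "must lie in (0, 1]")
  chk(cfg$seed_start >= 1 && cfg$seed_start < cfg$seed_end,
      "seed_start/seed_end", "must satisfy 1 <= seed_start < seed_end")
  chk(cfg$min_pathway_targets >= 1, "min_pathway_targets", "must be >= 1")
  chk(cfg$cluster_gap >= 0, "cluster_gap", "must be >= 0")
  chk(cfg$min_loop >= 1, "min_loop", "must be >= 1")
  chk(cfg$min_mature_paired >= 0 && cfg$min_mature_paired <= 1,
      "min_mature_paired", "must lie in [0, 1]")
  chk(cfg$min_helix_stack >= 1, "min_helix_stack", "must be >= 1")
  chk(cfg$precursor_upstream >= 0 && cfg$precursor_downstream >= 0,
      "precursor window", "must be >= 0")
  chk(cfg$pseudocount >= 0, "pseudocount", "must be >= 0")
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Absent file (or `NULL` path) yields all defaults. Keys present in the
#' file override the defaults; unknown keys are an error so typos do not
#' silently fall back to defaults. All invariants are re-checked.
#'
#' @param path Path to a YAML key-value file, or `NULL`.
#' @return A [pipeline_config()] object.
#' @export
load_config <- function(path = NULL) {
  defaults <- pipeline_config()
  if (is.null(path) || !nzchar(path)) return(defaults)
  if (!file.exists(path)) {
    stop("configuration error: file not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(defaults)
  unknown <- setdiff(names(vals), names(unclass(defaults)))
  if (length(unknown)) {
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}
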