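# QC cascade: length filter -> exact genome matching (both strands) ->
# known-miRNA panel -> other ncRNA -> unannotated. All cascade tallies
# are sums of collapsed read counts, not distinct sequences.

#' Classify collapsed reads through the QC cascade
#'
#' Each read is assigned the first matching category in order:
#' `too_short` (length below `min_read_length`), `unaligned` (no exact
#' match to the genome on either strand), `known_mirna` (full-length
#' exact equality with a panel mature sequence), `ncrna` (exact substring
#' of a non-miRNA ncRNA sequence), `unannotated`. Multi-mapping reads
#' keep all genome hits but contribute their count once.
#'
#' @param reads Data frame from [read_count_fasta()].
#' @param genome Named character vector of DNA chromosome sequences.
#' @param known_panel Annotation data frame (see
#'   [read_annotation_table()]).
#' @param ncrna_set Named character vector of RNA (or DNA) ncRNA
#'   sequences; may be empty.
#' @param config A [pipeline_config()].
#' @return A list with `classified` (one row per read: `read_id`,
#'   `sequence`, `count`, `category`, `matched_name`, `n_hits`, plus a
#'   `genome_hits` list column of 0-based half-open interval data
#'   frames) and `cascade` (a [qc_cascade()]).
#' @export
classify_reads <- function(reads, genome, known_panel, ncrna_set = character(0),
                           config = pipeline_config()) {
  if (length(genome) == 0L || all(!nzchar(genome))) {
    stop("validation error: empty genome", call. = FALSE)
  }
  genome <- toupper(genome)
  subjects <- lapply(genome, Biostrings::DNAString)
  panel_seqs <- known_panel$mature_sequence
  ncrna_set <- if (length(ncrna_set)) normalize_rna(ncrna_set) else character(0)

  n <- nrow(reads)
  category <- character(n)
  matched_name <- rep(NA_character_, n)
  hits_list <- vector("list", n)
  empty_hits <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    seq_rna <- reads$sequence[r]
    if (nchar(seq_rna) < config$min_read_length) {
      category[r] <- "too_short"
      hits_list[[r]] <- empty_hits
      next
    }
    hits <- genome_hits(seq_rna, subjects)
    hits_list[[r]] <- hits
    if (nrow(hits) == 0L) {
      category[r] <- "unaligned"
    } else if (seq_rna %in% panel_seqs) {
      category[r] <- "known_mirna"
      matched_name[r] <- known_panel$name[match(seq_rna, panel_seqs)]
    } else if (length(ncrna_set) &&
               any(vapply(ncrna_set, function(s) grepl(seq_rna, s, fixed = TRUE),
                          logical(1)))) {
      category[r] <- "ncrna"
    } else {
      category[r] <- "unannotated"
    }
  }
  classified <- data.frame(
    read_id = reads$read_id, sequence = reads$sequence, count = reads$count,
    category = category, matched_name = matched_name,
    n_hits = vapply(hits_list, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  classified$genome_hits <- hits_list
  cascade <- cascade_from_classified(classified)
  mf_log(paste0("classify_reads: raw=%.0f high_quality=%.0f ",
                "genome_matched=%.0f known=%.0f ncrna=%.0f unannotated=%.0f"),
         cascade$raw_reads, cascade$high_quality_reads,
         cascade$genome_matched, cascade$known_mirna_matched,
         cascade$ncrna_matched, cascade$remaining_for_discovery)
  list(classified = classified, cascade = cascade)
}

# Exact hits of an RNA read against DNA chromosomes, both strands.
# Coordinates are 0-based half-open on the forward genome.
genome_hits <- function(seq_rna, subjects) {
  d <- rna_to_dna(seq_rna)
  pat_fwd <- Biostrings::DNAString(d)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  out <- list()
  k <- nchar(d)
  for (chrom in names(subjects)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_fwd else pat_rev
      m <- Biostrings::matchPattern(pat, subjects[[chrom]])
      starts <- Biostrings::start(m)
      if (length(starts)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = starts - 1L, end = starts - 1L + k,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Construct a QC cascade summary
#'
#' All tallies are sums of collapsed read counts. The cascade must be
#' internally consistent: raw >= high-quality >= genome-matched >=
#' known-miRNA, and the genome-matched reads partition into known miRNA,
#' other ncRNA and reads remaining for discovery.
#'
#' @param raw_reads,high_quality_reads,genome_matched,known_mirna_matched,ncrna_matched,remaining_for_discovery
#'   Stage tallies (numbers of reads).
#' @return An object of class `qc_cascade` with the tallies and the
#'   stage-over-stage percentages (`fractions`), rounded half-up to two
#'   decimals.
#' @export
#' @examples
#' qc_cascade(99354224, 85252341, 74678115, 61587749, 4335108,
#'            8755258)$fractions
qc_cascade <- function(raw_reads, high_quality_reads, genome_matched,
                       known_mirna_matched, ncrna_matched,
                       remaining_for_discovery) {
  x <- list(raw_reads = raw_reads,
            high_quality_reads = high_quality_reads,
            genome_matched = genome_matched,
            known_mirna_matched = known_mirna_matched,
            ncrna_matched = ncrna_matched,
            remaining_for_discovery = remaining_for_discovery)
  if (!(raw_reads >= high_quality_reads &&
        high_quality_reads >= genome_matched &&
        genome_matched >= known_mirna_matched)) {
    stop("internal error: QC cascade tallies are not monotone",
         call. = FALSE)
  }
  if (genome_matched !=
      known_mirna_matched + ncrna_matched + remaining_for_discovery) {
    stop("internal error: genome-matched reads do not partition",
         call. = FALSE)
  }
  x$fractions <- qc_fractions(raw_reads, high_quality_reads, genome_matched,
                              known_mirna_matched)
  class(x) <- "qc_cascade"
  x
}

#' Stage-over-stage QC percentages
#'
#' @param raw_reads,high_quality_reads,genome_matched,known_mirna_matched
#'   Cascade tallies.
#' @return Named numeric vector: `high_quality_pct` (of raw),
#'   `genome_pct` (of high quality), `known_pct` (of genome-matched),
#'   each rounded half-up to 2 decimals.
#' @export
#' @examples
#' qc_fractions(99354224, 85252341, 74678115, 61587749)
qc_fractions <- function(raw_reads, high_quality_reads, genome_matched,
                         known_mirna_matched) {
  safe <- function(num, den) if (den > 0) percent(num, den) else NA_real_
  c(high_quality_pct = safe(high_quality_reads, raw_reads),
    genome_pct = safe(genome_matched, high_quality_reads),
    known_pct = safe(known_mirna_matched, genome_matched))
}

cascade_from_classified <- function(classified) {
  tot <- function(cat) sum(classified$count[classified$category == cat])
  raw <- sum(classified$count)
  known <- tot("known_mirna"); ncr <- tot("ncrna"); unann <- tot("unannotated")
  genome <- known + ncr + unann
  hq <- raw - tot("too_short")
  qc_cascade(raw, hq, genome, known, ncr, unann)
}

#' Tabulate a QC cascade as a stage-by-stage report
#'
#' One row per stage with the read tally and the percentage of the
#' relevant parent stage (half-up, 2 decimals); also logged at INFO.
#'
#' @param cascade A [qc_cascade()].
#' @return Data frame with columns `stage`, `reads`, `percent_of`,
#'   `percent`.
#' @export
qc_report <- function(cascade) {
  stopifnot(inherits(cascade, "qc_cascade"))
  f <- cascade$fractions
  df <- data.frame(
    stage = c("raw", "high_quality", "genome_matched", "known_mirna",
              "ncrna", "remaining_for_discovery"),
    reads = c(cascade$raw_reads, cascade$high_quality_reads,
              cascade$genome_matched, cascade$known_mirna_matched,
              cascade$ncrna_matched, cascade$remaining_for_discovery),
    percent_of = c(NA, "raw", "high_quality", "genome_matched",
                   "genome_matched", "genome_matched"),
    percent = c(NA, f[["high_quality_pct"]], f[["genome_pct"]],
                f[["known_pct"]],
                if (cascade$genome_matched > 0)
                  percent(cascade$ncrna_matched, cascade$genome_matched)
                else NA_real_,
                if (cascade$genome_matched > 0)
                  percent(cascade$remaining_for_discovery,
                          cascade$genome_matched)
                else NA_real_),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(df))) {
    mf_log("qc_report: %s reads=%.0f pct=%s", df$stage[i], df$reads[i],
           ifelse(is.na(df$percent[i]), "-", format(df$percent[i])))
  }
  df
}
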