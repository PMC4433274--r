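# Readers and writers for the pipeline's file formats. FASTA parsing is
# delegated to Biostrings; this layer adds the count-encoded header
# dialect, alphabet normalization and validation.

READ_ID_DIALECT <- "^seq-[0-9]+_x([0-9]+)$"

#' Read collapsed small-RNA reads from a count-encoded FASTA file
#'
#' Headers of the form `seq-<rank>_x<count>` carry the collapsed read
#' multiplicity (e.g. `seq-915_x4024` is a unique sequence observed 4024
#' times); other headers default to count 1, unless they carry an
#' explicit ` x=<count>` attribute as written by [write_count_fasta()].
#' Sequences are normalized to the RNA alphabet (T mapped to U).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `read_id`, `sequence` (RNA) and
#'   `count` (integer >= 1).
#' @export
read_count_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("format error in FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  first_tok <- sub("[[:space:]].*$", "", headers)
  count <- rep(NA_integer_, length(set))
  dialect <- grepl(READ_ID_DIALECT, first_tok)
  count[dialect] <- as.integer(sub(READ_ID_DIALECT, "\\1", first_tok[dialect]))
  m <- regexpr(" x=[0-9]+$", headers)
  has_attr <- m > 0L
  attr_val <- rep(NA_integer_, length(headers))
  attr_val[has_attr] <- as.integer(sub("^ x=", "", regmatches(headers, m)))
  count[!dialect & has_attr] <- attr_val[!dialect & has_attr]
  count[is.na(count)] <- 1L
  if (any(count < 1L)) {
    bad <- first_tok[count < 1L][1L]
    stop("validation error: read count must be >= 1 (header ", bad, ")",
         call. = FALSE)
  }
  reads <- data.frame(
    read_id = unname(first_tok),
    sequence = unname(normalize_rna(as.character(set))),
    count = unname(count),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  mf_log("read_count_fasta: %d records, %d total reads from %s",
         nrow(reads), sum(reads$count), path)
  reads
}

#' Write collapsed reads to FASTA
#'
#' Inverse of [read_count_fasta()]: ids in the `seq-<rank>_x<count>`
#' dialect are written as-is (after checking the encoded count matches);
#' other ids with count > 1 gain an ` x=<count>` header attribute so the
#' round trip is exact.
#'
#' @param reads Data frame with `read_id`, `sequence`, `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_fasta <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "count") %in% names(reads)))
  dialect <- grepl(READ_ID_DIALECT, reads$read_id)
  enc <- suppressWarnings(
    as.integer(sub(READ_ID_DIALECT, "\\1", reads$read_id)))
  if (any(dialect & enc != reads$count)) {
    stop("validation error: read_id count suffix disagrees with count field",
         call. = FALSE)
  }
  headers <- ifelse(dialect | reads$count == 1L,
                    reads$read_id,
                    paste0(reads$read_id, " x=", reads$count))
  seqs <- Biostrings::BStringSet(reads$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a genome (or any DNA FASTA) as a named character vector
#'
#' @param path Path to a DNA FASTA file.
#' @return Named character vector, upper-case DNA, one element per
#'   chromosome/sequence.
#' @export
read_genome_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("format error in FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- toupper(as.character(set))
  names(out) <- sub("[[:space:]].*$", "", names(set))
  out
}

#' Read an RNA sequence set (ncRNA, 3'UTRs) as a named character vector
#'
#' Input may be written in DNA or RNA alphabet; sequences are normalized
#' to RNA.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_rna_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("format error in FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- normalize_rna(as.character(set))
  names(out) <- sub("[[:space:]].*$", "", names(set))
  out
}

#' Write a named character vector of sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a known-miRNA annotation table
#'
#' Tab-separated with required columns `name`, `species`,
#' `mature_sequence` and optional locus columns `chrom`, `start`, `end`,
#' `strand` (0-based half-open). Mature sequences are normalized to RNA
#' and must be at least 9 nt so a seed at positions 2-8 exists; when the
#' name carries a 3-letter species prefix (e.g. `hsa-miR-34a-5p`) it must
#' agree with the `species` column.
#'
#' @param path Path to a TSV file.
#' @return Data frame of annotations (empty file yields 0 rows).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L)) == 0L) {
    return(empty_annotation())
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "species", "mature_sequence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error: annotation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(empty_annotation())
  df$mature_sequence <- normalize_rna(df$mature_sequence)
  validate_annotation(df)
}

empty_annotation <- function() {
  data.frame(name = character(0), species = character(0),
             mature_sequence = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

validate_annotation <- function(df) {
  short <- nchar(df$mature_sequence) < 9L
  if (any(short)) {
    stop("validation error: mature_sequence shorter than 9 nt for ",
         df$name[short][1L], " (no seed at positions 2-8)", call. = FALSE)
  }
  prefixed <- grepl("^[a-z]{3}-", df$name)
  pref <- substr(df$name, 1L, 3L)
  bad <- prefixed & pref != df$species
  if (any(bad)) {
    stop("validation error: species code does not match name prefix for ",
         df$name[bad][1L], call. = FALSE)
  }
  has_locus <- all(c("chrom", "start", "end", "strand") %in% names(df))
  if (has_locus) {
    with_locus <- !is.na(df$chrom) & nzchar(df$chrom)
    if (any(with_locus & !(df$start < df$end))) {
      bad <- df$name[with_locus & !(df$start < df$end)][1L]
      stop("validation error: locus start >= end for ", bad, call. = FALSE)
    }
    if (any(with_locus & !df$strand %in% c("+", "-"))) {
      stop("validation error: strand must be '+' or '-'", call. = FALSE)
    }
  } else {
    df$chrom <- NA_character_; df$start <- NA_integer_
    df$end <- NA_integer_; df$strand <- NA_character_
  }
  df
}

#' Write an annotation table to TSV
#' @param df Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pathway gene set (one gene id per line)
#' @param path Path to a plain-text file.
#' @return Character vector of gene ids (blank lines and `#` comments
#'   dropped).
#' @export
read_pathway_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a qPCR Ct table
#'
#' Tab-separated with columns `target_id`, `sample_id`, `group`
#' (`mid`/`late`), `replicate`, `ct`.
#'
#' @param path Path to a TSV file.
#' @return Data frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("target_id", "sample_id", "group", "replicate", "ct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error: Ct table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$ct <= 0)) stop("validation error: Ct values must be > 0",
                            call. = FALSE)
  df
}
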