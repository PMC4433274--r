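# Novel-miRNA candidate discovery: a transparent, rule-based stand-in
# for probabilistic discovery tools. Unannotated genome-matched reads
# are grouped into loci, a precursor window is excised around the
# highest-count read, and the window must fold into a plausible single
# stem-loop (maximum-weight nested base pairing, Nussinov-style dynamic
# programming) carrying the mature on one arm. Candidates also need at
# least `min_candidate_count` supporting reads.

PAIR_WEIGHTS <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)

pair_weight <- function(a, b) {
  w <- PAIR_WEIGHTS[paste0(a, b)]
  ifelse(is.na(w), 0, w)
}

#' Fold an RNA sequence by maximum-weight nested base pairing
#'
#' Nussinov-style dynamic programming maximizing total pair weight
#' (GC = 3, AU = 2, GU = 1) over pseudoknot-free structures with hairpin
#' loops of at least `min_loop` unpaired bases. The score is a monotone
#' proxy for thermodynamic stability, not a free energy;
#' `energy_score = -(total weight)` so more negative means more stable.
#' Traceback is deterministic: on score ties the 3' base is left
#' unpaired, and among pairing partners the smallest 5' index wins.
#'
#' @param sequence RNA (or DNA) string; length must be at least
#'   `min_loop + 2`.
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return An object of class `hairpin_fold`: `sequence`, `pairing`
#'   (two-column matrix of 1-based i < j index pairs), `n_pairs`,
#'   `energy_score`, `dot_bracket`.
#' @export
#' @examples
#' fold_nussinov("GGGAAACCC")$n_pairs  # 3
fold_nussinov <- function(sequence, min_loop = 3L) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (n < min_loop + 2L) {
    stop("validation error: sequence shorter than min_loop + 2",
         call. = FALSE)
  }
  ch <- strsplit(sequence, "")[[1]]
  W <- matrix(0, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- W[i, j - 1L]
      ks <- i:(j - min_loop - 1L)
      wk <- pair_weight(ch[ks], ch[j])
      ok <- wk > 0
      if (any(ok)) {
        ks_ok <- ks[ok]
        left <- numeric(length(ks_ok))
        gt <- ks_ok > i
        if (any(gt)) left[gt] <- W[i, ks_ok[gt] - 1L]
        inner <- W[cbind(ks_ok + 1L, j - 1L)]
        best <- max(best, max(wk[ok] + left + inner))
      }
      W[i, j] <- best
    }
  }
  pairs <- matrix(integer(0), ncol = 2L)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i <= min_loop) next
    if (W[i, j] == W[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      w <- pair_weight(ch[k], ch[j])
      if (w == 0) next
      left <- if (k > i) W[i, k - 1L] else 0
      if (left + w + W[k + 1L, j - 1L] == W[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  db <- rep(".", n)
  db[pairs[, 1L]] <- "("; db[pairs[, 2L]] <- ")"
  total <- if (nrow(pairs)) sum(pair_weight(ch[pairs[, 1L]], ch[pairs[, 2L]]))
           else 0
  structure(list(sequence = sequence, pairing = pairs,
                 n_pairs = nrow(pairs), energy_score = -total,
                 dot_bracket = paste(db, collapse = "")),
            class = "hairpin_fold")
}

# Group pairs (sorted by 5' index) into helices: maximal runs of
# directly stacked pairs (i+1, j-1).
helix_membership <- function(pairs) {
  if (nrow(pairs) == 0L) return(integer(0))
  helix <- integer(nrow(pairs))
  helix[1L] <- 1L
  for (t in seq_len(nrow(pairs) - 1L)) {
    stacked <- pairs[t + 1L, 1L] == pairs[t, 1L] + 1L &&
               pairs[t + 1L, 2L] == pairs[t, 2L] - 1L
    helix[t + 1L] <- if (stacked) helix[t] else helix[t] + 1L
  }
  helix
}

#' Assess whether a precursor folds into a plausible miRNA hairpin
#'
#' The precursor is folded with [fold_nussinov()]; `is_hairpin` is true
#' iff (a) the fold is a single stem-loop — after discarding incidental
#' helices shorter than `min_helix_stack` stacked pairs, the remaining
#' pairs form one contiguous nesting chain with no disjoint helices;
#' (b) the mature sequence lies entirely on one arm, strictly 5' or 3'
#' of the terminal loop; and (c) at least `min_mature_paired` of the
#' mature bases are paired within those surviving stem helices.
#'
#' @param precursor RNA string containing the mature exactly once.
#' @param mature RNA string of the mature miRNA.
#' @param config A [pipeline_config()] (uses `min_loop`,
#'   `min_helix_stack`, `min_mature_paired`).
#' @return A list (class `hairpin_assessment`) with the fold plus
#'   `mature_arm` (`"5p"`, `"3p"` or `NA`), `mature_paired_fraction`,
#'   `single_stem`, `is_hairpin`.
#' @export
assess_hairpin <- function(precursor, mature, config = pipeline_config()) {
  precursor <- normalize_rna(precursor)
  mature <- normalize_rna(mature)
  occ <- count_occurrences(mature, precursor)
  if (occ != 1L) {
    stop("validation error: mature must occur exactly once in precursor ",
         "(found ", occ, ")", call. = FALSE)
  }
  m1 <- regexpr(mature, precursor, fixed = TRUE)[1L]
  m2 <- m1 + nchar(mature) - 1L
  fold <- fold_nussinov(precursor, min_loop = config$min_loop)
  pairs <- fold$pairing

  helix <- helix_membership(pairs)
  keep <- helix %in% which(tabulate(helix) >= config$min_helix_stack)
  stem <- pairs[keep, , drop = FALSE]
  # fraction of mature bases paired within the stem (incidental short
  # helices do not count): discriminates real arms from dense but
  # fragmented pairing of random sequence
  stem_pos <- c(stem[, 1L], stem[, 2L])
  mature_paired_fraction <-
    sum(stem_pos >= m1 & stem_pos <= m2) / nchar(mature)
  single_stem <- nrow(stem) > 0L
  if (single_stem && nrow(stem) > 1L) {
    # sorted by 5' index; a disjoint neighbour means a second stem
    single_stem <- all(stem[-1L, 1L] < stem[-nrow(stem), 2L])
  }
  mature_arm <- NA_character_
  if (single_stem) {
    loop5 <- max(stem[, 1L])   # innermost pair bounds the terminal loop
    loop3 <- min(stem[, 2L])
    if (m2 <= loop5) mature_arm <- "5p"
    else if (m1 >= loop3) mature_arm <- "3p"
  }
  is_hairpin <- single_stem && !is.na(mature_arm) &&
    mature_paired_fraction >= config$min_mature_paired
  structure(list(precursor_sequence = precursor, mature_sequence = mature,
                 pairing = pairs, n_pairs = fold$n_pairs,
                 energy_score = fold$energy_score,
                 dot_bracket = fold$dot_bracket,
                 mature_start = m1, mature_end = m2,
                 mature_arm = mature_arm,
                 mature_paired_fraction = mature_paired_fraction,
                 single_stem = single_stem, is_hairpin = is_hairpin),
            class = "hairpin_assessment")
}

# Excise [start, end) (0-based half-open, clamped) from a chromosome;
# minus-strand windows are reverse-complemented. Returns RNA.
excise_window <- function(genome, chrom, start, end, strand) {
  len <- nchar(genome[[chrom]])
  start <- max(0L, start); end <- min(len, end)
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp_dna(s)
  list(sequence = normalize_rna(s), start = start, end = end)
}

#' Discover novel miRNA candidates from unannotated reads
#'
#' Unannotated genome-matched reads are grouped into loci by
#' single-linkage chaining of their genome hits (hits overlapping or
#' within `locus_merge_gap` nt join). Per locus the highest-count read is
#' taken as the putative mature; the precursor is the genomic window
#' from `precursor_upstream` nt upstream to `precursor_downstream` nt
#' downstream of the mature on its strand, and the mirrored window is
#' also tried — the better hairpin wins. A candidate is retained iff the
#' precursor passes [assess_hairpin()] and the locus total read count is
#' at least `min_candidate_count`. Retained candidates are ranked by
#' descending total count and named `seq-<rank>_x<count>`.
#'
#' @param classified Classification data frame from [classify_reads()]
#'   (rows with other categories are ignored).
#' @param genome Named character vector of DNA chromosomes.
#' @param config A [pipeline_config()].
#' @param per_sample_counts Optional numeric matrix (sequence x sample)
#'   giving per-sample counts for each read sequence; when supplied,
#'   per-sample candidate counts are summed over the locus reads.
#' @return Data frame with one row per retained candidate:
#'   `candidate_id`, `mature_sequence`, `chrom`, `start`, `end`,
#'   `strand` (precursor locus, 0-based half-open), `mature_arm`,
#'   `n_pairs`, `energy_score`, `mature_paired_fraction`, `total_count`,
#'   a `member_sequences` list column, per-sample count columns when
#'   available, and a `dot_bracket` column. An attribute `"loci"` holds
#'   the per-locus pre-filter table (including rejected loci).
#' @export
discover_candidates <- function(classified, genome,
                                config = pipeline_config(),
                                per_sample_counts = NULL) {
  un <- classified[classified$category == "unannotated" &
                   classified$n_hits > 0L, , drop = FALSE]
  empty <- data.frame(candidate_id = character(0),
                      mature_sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mature_arm = character(0),
                      n_pairs = integer(0), energy_score = numeric(0),
                      mature_paired_fraction = numeric(0),
                      total_count = integer(0), dot_bracket = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(un) == 0L) {
    attr(empty, "loci") <- empty
    return(empty)
  }
  # expand (read, hit) pairs
  hits <- do.call(rbind, lapply(seq_len(nrow(un)), function(r) {
    h <- un$genome_hits[[r]]
    h$row <- r
    h
  }))
  # single-linkage locus grouping per chromosome, strand-blind
  hits <- hits[order(hits$chrom, hits$start), ]
  locus <- integer(nrow(hits))
  cur <- 0L; max_end <- -Inf; cur_chrom <- ""
  for (t in seq_len(nrow(hits))) {
    if (hits$chrom[t] != cur_chrom ||
        hits$start[t] - max_end > config$locus_merge_gap) {
      cur <- cur + 1L
      cur_chrom <- hits$chrom[t]
      max_end <- hits$end[t]
    } else {
      max_end <- max(max_end, hits$end[t])
    }
    locus[t] <- cur
  }
  hits$locus <- locus

  loci_rows <- list()
  for (L in unique(hits$locus)) {
    lh <- hits[hits$locus == L, , drop = FALSE]
    rows <- unique(lh$row)
    reads <- un[rows, , drop = FALSE]
    total <- sum(reads$count)
    # putative mature: highest count, ties broken by sequence
    ord <- order(-reads$count, reads$sequence)
    mature <- reads$sequence[ord[1L]]
    mrow <- rows[ord[1L]]
    mhit <- lh[lh$row == mrow, , drop = FALSE][1L, ]
    u <- config$precursor_upstream; d <- config$precursor_downstream
    if (mhit$strand == "+") {
      w1 <- c(mhit$start - u, mhit$end + d)
      w2 <- c(mhit$start - d, mhit$end + u)
    } else {
      w1 <- c(mhit$start - d, mhit$end + u)
      w2 <- c(mhit$start - u, mhit$end + d)
    }
    best <- NULL; best_win <- NULL
    for (w in list(w1, w2)) {
      ex <- excise_window(genome, mhit$chrom, w[1L], w[2L], mhit$strand)
      if (count_occurrences(mature, ex$sequence) != 1L) next
      hp <- assess_hairpin(ex$sequence, mature, config)
      better <- is.null(best) ||
        (hp$is_hairpin && !best$is_hairpin) ||
        (hp$is_hairpin == best$is_hairpin &&
         hp$energy_score < best$energy_score)
      if (better) { best <- hp; best_win <- ex }
    }
    if (is.null(best)) next
    row <- data.frame(
      mature_sequence = mature, chrom = mhit$chrom,
      start = best_win$start, end = best_win$end, strand = mhit$strand,
      mature_arm = best$mature_arm, n_pairs = best$n_pairs,
      energy_score = best$energy_score,
      mature_paired_fraction = best$mature_paired_fraction,
      total_count = total, is_hairpin = best$is_hairpin,
      dot_bracket = best$dot_bracket, stringsAsFactors = FALSE)
    row$member_sequences <- list(reads$sequence)
    loci_rows[[length(loci_rows) + 1L]] <- row
  }
  if (!length(loci_rows)) {
    attr(empty, "loci") <- empty
    return(empty)
  }
  loci_df <- do.call(rbind, loci_rows)
  keep <- loci_df$is_hairpin & loci_df$total_count >= config$min_candidate_count
  out <- loci_df[keep, , drop = FALSE]
  out <- out[order(-out$total_count, out$mature_sequence), , drop = FALSE]
  if (nrow(out)) {
    out <- cbind(candidate_id = sprintf("seq-%d_x%d", seq_len(nrow(out)),
                                        out$total_count),
                 out, stringsAsFactors = FALSE)
    if (!is.null(per_sample_counts)) {
      persample <- t(vapply(out$member_sequences, function(seqs) {
        colSums(per_sample_counts[intersect(seqs,
                                            rownames(per_sample_counts)),
                                  , drop = FALSE])
      }, numeric(ncol(per_sample_counts))))
      colnames(persample) <- paste0("count_", colnames(per_sample_counts))
      out <- cbind(out, persample)
    }
  } else {
    out <- cbind(candidate_id = character(0), out)
  }
  rownames(out) <- NULL
  out$is_hairpin <- NULL
  mf_log("discover_candidates: %d loci, %d retained candidates",
         nrow(loci_df), nrow(out))
  attr(out, "loci") <- loci_df
  out
}
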