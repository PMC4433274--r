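# Synthetic-data generator emulating the study design: a toy genome
# with embedded known miRNAs, stem-loop precursors of novel miRNAs,
# shuffled decoy loci and ncRNAs; two groups of three samples with
# planted fold changes and negative-binomial count noise; 3'UTRs with
# planted seed-complement sites and a pathway gene set. Every planted
# entity is recorded in a ground-truth object so downstream stages can
# be validated end to end.

#' Specify a synthetic small RNA-seq study
#'
#' Defaults emulate the study design at desk scale: two groups of three
#' samples, per-sample genome-matched depth around 200,000 reads (the
#' study's 12-13 million scaled down ~60x), planted fold changes of 4.0
#' (up) and 0.25 (down) — both beyond the 2.0-fold gate — and mild
#' negative-binomial overdispersion (0.1) typical of human biological
#' replicates.
#'
#' @param n_chromosomes,chrom_length Toy genome shape (default 3 x
#'   10 kb).
#' @param n_known_mirnas Known miRNAs embedded in the genome
#'   (default 60).
#' @param n_novel_hairpins Novel stem-loop precursors embedded
#'   (default 8).
#' @param n_decoy_loci Shuffled, non-folding decoy loci (default 10).
#' @param n_ncrnas Non-miRNA ncRNA sequences embedded (default 5).
#' @param n_foreign_homologs Panel entries from other species sharing a
#'   novel hairpin's seed (default 5), for conservation demonstrations.
#' @param n_samples_per_group Samples per group (default 3).
#' @param depth_per_sample Expected genome-matched reads per sample
#'   (default 2e5); per-sample depth factors are drawn within +/-10%.
#' @param planted_fold_changes Optional named vector mapping miRNA ids
#'   (known names or `novel-hp-<i>`) to late/mid ratios; `NULL` assigns
#'   `fold_up` to a fraction `prop_up` and `fold_down` to `prop_down`
#'   of ids at random.
#' @param prop_up,prop_down,fold_up,fold_down Automatic fold-change
#'   assignment (defaults 10% up at 4.0, 15% down at 0.25).
#' @param dispersion Negative-binomial overdispersion of counts
#'   (variance `mu + dispersion * mu^2`); 0 gives deterministic counts
#'   equal to the rounded means (default 0.1).
#' @param n_utrs Number of genes with simulated 3'UTRs (default 30;
#'   at least the 8 pathway genes).
#' @param planted_sites Optional named list mapping miRNA id to a
#'   character vector of target gene ids; `NULL` plants sites so that
#'   most differentially expressed novel candidates target 2 pathway
#'   genes (with single-gene boundary cases).
#' @param rng_seed Integer seed making all outputs reproducible.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_chromosomes = 3L, chrom_length = 10000L,
                            n_known_mirnas = 60L, n_novel_hairpins = 8L,
                            n_decoy_loci = 10L, n_ncrnas = 5L,
                            n_foreign_homologs = 5L,
                            n_samples_per_group = 3L,
                            depth_per_sample = 2e5,
                            planted_fold_changes = NULL,
                            prop_up = 0.10, prop_down = 0.15,
                            fold_up = 4.0, fold_down = 0.25,
                            dispersion = 0.1, n_utrs = 30L,
                            planted_sites = NULL, rng_seed = 1L) {
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chrom_length = as.integer(chrom_length),
               n_known_mirnas = as.integer(n_known_mirnas),
               n_novel_hairpins = as.integer(n_novel_hairpins),
               n_decoy_loci = as.integer(n_decoy_loci),
               n_ncrnas = as.integer(n_ncrnas),
               n_foreign_homologs = as.integer(n_foreign_homologs),
               n_samples_per_group = as.integer(n_samples_per_group),
               depth_per_sample = depth_per_sample,
               planted_fold_changes = planted_fold_changes,
               prop_up = prop_up, prop_down = prop_down,
               fold_up = fold_up, fold_down = fold_down,
               dispersion = dispersion, n_utrs = as.integer(n_utrs),
               planted_sites = planted_sites,
               rng_seed = as.integer(rng_seed))
  with(spec, {
    stopifnot(n_chromosomes >= 1, chrom_length >= 1000,
              n_known_mirnas >= 1, n_novel_hairpins >= 0,
              n_decoy_loci >= 0, n_ncrnas >= 0,
              n_samples_per_group >= 2, depth_per_sample > 0,
              dispersion >= 0, n_utrs >= 8,
              fold_up > 0, fold_down > 0,
              prop_up >= 0, prop_down >= 0, prop_up + prop_down <= 1)
  })
  if (!is.null(spec$planted_fold_changes) &&
      any(spec$planted_fold_changes <= 0)) {
    stop("validation error: planted fold changes must be > 0",
         call. = FALSE)
  }
  class(spec) <- "simulation_spec"
  spec
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Count genome occurrences of a DNA pattern on both strands (C-level).
genome_pattern_count <- function(pattern_dna, genome_set) {
  pat <- Biostrings::DNAString(pattern_dna)
  sum(Biostrings::vcountPattern(pat, genome_set)) +
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                  genome_set))
}

mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# Resolve per-id late/mid ratios: explicit mapping wins, otherwise
# random assignment of fold_up / fold_down to the configured fractions.
resolve_ratios <- function(ids, spec) {
  ratios <- stats::setNames(rep(1, length(ids)), ids)
  if (!is.null(spec$planted_fold_changes)) {
    hit <- intersect(names(spec$planted_fold_changes), ids)
    ratios[hit] <- spec$planted_fold_changes[hit]
    return(ratios)
  }
  n <- length(ids)
  n_up <- round(spec$prop_up * n); n_down <- round(spec$prop_down * n)
  idx <- sample(n)
  if (n_up > 0) ratios[idx[seq_len(n_up)]] <- spec$fold_up
  if (n_down > 0) ratios[idx[n_up + seq_len(n_down)]] <- spec$fold_down
  ratios
}

#' Simulate a toy genome with embedded miRNA annotation
#'
#' Builds a random genome and embeds, at recorded non-overlapping loci:
#' known miRNA mature sequences (22 nt), novel stem-loop precursors
#' (22 nt arm, 8 nt loop, reverse-complement arm with up to 2
#' mismatches; each screened at generation to pass [assess_hairpin()]
#' on its discovery excision window), shuffled non-folding decoy loci,
#' and ncRNA sequences. Mature sequences are screened to occur exactly
#' once in the genome. The annotation panel additionally carries
#' other-species homologs sharing a novel hairpin's seed (not embedded
#' in the genome).
#'
#' @param spec A [simulation_spec()].
#' @return List with `genome` (named DNA character vector),
#'   `annotation` (panel data frame), `ncrna` (named RNA character
#'   vector) and `truth` (known loci and ratios, hairpin loci, arms and
#'   ratios, decoy loci).
#' @export
simulate_genome_and_annotation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed)
  cfg <- pipeline_config()
  genome <- stats::setNames(
    vapply(seq_len(spec$n_chromosomes), function(i)
      rand_seq(spec$chrom_length), ""),
    paste0("chr", seq_len(spec$n_chromosomes)))

  slot_step <- 250L
  slots <- do.call(rbind, lapply(names(genome), function(ch) {
    starts <- seq(100L, spec$chrom_length - 160L, by = slot_step)
    data.frame(chrom = ch, pos = starts, stringsAsFactors = FALSE)
  }))
  needed <- spec$n_known_mirnas + spec$n_novel_hairpins +
    spec$n_decoy_loci + spec$n_ncrnas
  if (nrow(slots) < needed) {
    stop("generation error: genome too small for requested loci (",
         nrow(slots), " slots < ", needed, ")", call. = FALSE)
  }
  slots <- slots[sample(nrow(slots)), ]
  slot_i <- 0L
  next_slot <- function() {
    slot_i <<- slot_i + 1L
    slots[slot_i, ]
  }
  embed_at <- function(g, chrom, pos, seq) {
    substr(g[[chrom]], pos + 1L, pos + nchar(seq)) <- seq
    g
  }
  genome_set <- function() Biostrings::DNAStringSet(genome)

  # --- known miRNAs ---
  known_names <- sprintf("hsa-mir-sim-%03d", seq_len(spec$n_known_mirnas))
  known <- data.frame(name = known_names, chrom = "", start = 0L, end = 0L,
                      strand = "+", sequence = "", stringsAsFactors = FALSE)
  matures <- character(0)
  for (i in seq_len(spec$n_known_mirnas)) {
    s <- next_slot()
    for (try in 1:50) {
      m <- rand_seq(22L)
      genome <- embed_at(genome, s$chrom, s$pos, m)
      if (!(m %in% matures) &&
          genome_pattern_count(m, genome_set()) == 1L) break
      if (try == 50) stop("generation error: could not embed unique mature",
                          call. = FALSE)
    }
    matures <- c(matures, m)
    known$chrom[i] <- s$chrom; known$start[i] <- s$pos
    known$end[i] <- s$pos + 22L; known$sequence[i] <- m
  }

  # --- novel hairpin precursors ---
  hp <- data.frame(hp_id = character(0), chrom = character(0),
                   prec_start = integer(0), prec_end = integer(0),
                   mature_start = integer(0), mature_end = integer(0),
                   strand = character(0), mature_arm = character(0),
                   mature_sequence = character(0),
                   precursor_sequence = character(0),
                   stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_novel_hairpins)) {
    s <- next_slot()
    placed <- FALSE
    for (try in 1:80) {
      # re-draw the flanking genome too: a fixed flank can carry a helix
      # that defeats the single-stem test for every hairpin redraw
      genome <- embed_at(genome, s$chrom, s$pos - 60L, rand_seq(60L))
      genome <- embed_at(genome, s$chrom, s$pos + 52L, rand_seq(60L))
      arm <- rand_seq(22L)
      loop <- rand_seq(8L)
      arm2 <- revcomp_dna(arm)
      n_mm <- sample(0:2, 1L)
      if (n_mm > 0) arm2 <- mutate_positions(arm2, sample(22L, n_mm))
      arm_choice <- sample(c("5p", "3p"), 1L)
      prec <- paste0(arm, loop, arm2)
      mature_off <- if (arm_choice == "5p") 0L else 30L
      mature_dna <- substr(prec, mature_off + 1L, mature_off + 22L)
      genome <- embed_at(genome, s$chrom, s$pos, prec)
      ms <- s$pos + mature_off; me <- ms + 22L
      if (genome_pattern_count(mature_dna, genome_set()) != 1L) next
      win <- excise_window(genome, s$chrom,
                           ms - cfg$precursor_upstream,
                           me + cfg$precursor_downstream, "+")
      mature_rna <- normalize_rna(mature_dna)
      if (count_occurrences(mature_rna, win$sequence) != 1L) next
      hpa <- assess_hairpin(win$sequence, mature_rna, cfg)
      if (!hpa$is_hairpin) next
      hp <- rbind(hp, data.frame(
        hp_id = paste0("novel-hp-", i), chrom = s$chrom,
        prec_start = s$pos, prec_end = s$pos + nchar(prec),
        mature_start = ms, mature_end = me, strand = "+",
        mature_arm = arm_choice, mature_sequence = mature_rna,
        precursor_sequence = normalize_rna(prec),
        stringsAsFactors = FALSE))
      matures <- c(matures, mature_dna)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("generation error: could not construct hairpin ", i,
           " after 80 attempts", call. = FALSE)
    }
  }

  # --- decoy loci: shuffled (non-folding) sequence, unscreened ---
  decoys <- data.frame(decoy_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_decoy_loci)) {
    s <- next_slot()
    arm <- rand_seq(22L)
    template <- paste0(arm, rand_seq(8L), revcomp_dna(arm))
    shuffled <- paste(sample(strsplit(template, "")[[1]]), collapse = "")
    genome <- embed_at(genome, s$chrom, s$pos, shuffled)
    decoys <- rbind(decoys, data.frame(
      decoy_id = paste0("decoy-", i), chrom = s$chrom, start = s$pos,
      end = s$pos + nchar(shuffled), stringsAsFactors = FALSE))
  }

  # --- ncRNAs (embedded so their reads are genome-matched) ---
  ncrna <- character(0)
  for (i in seq_len(spec$n_ncrnas)) {
    s <- next_slot()
    seq80 <- rand_seq(80L)
    genome <- embed_at(genome, s$chrom, s$pos, seq80)
    ncrna <- c(ncrna, stats::setNames(normalize_rna(seq80),
                                      paste0("ncrna-", i)))
  }

  # --- other-species homologs sharing a hairpin seed ---
  foreign <- NULL
  n_foreign <- min(spec$n_foreign_homologs, nrow(hp))
  if (n_foreign > 0) {
    species_pool <- c("mmu", "gga", "bta", "cfa", "rno")
    rows <- lapply(seq_len(n_foreign), function(j) {
      mat <- hp$mature_sequence[j]
      sp <- sample(species_pool, 1L)
      for (try in 1:50) {
        # keep seed positions 2-8; mutate ~35% of the rest
        other_pos <- setdiff(seq_len(nchar(mat)), 2:8)
        n_mut <- max(1L, round(0.35 * length(other_pos)))
        hom_dna <- mutate_positions(rna_to_dna(mat),
                                    sample(other_pos, n_mut))
        if (!(hom_dna %in% matures) &&
            genome_pattern_count(hom_dna, genome_set()) == 0L) {
          return(data.frame(name = sprintf("%s-mir-sim-f%02d", sp, j),
                            species = sp,
                            mature_sequence = normalize_rna(hom_dna),
                            chrom = NA_character_, start = NA_integer_,
                            end = NA_integer_, strand = NA_character_,
                            stringsAsFactors = FALSE))
        }
      }
      stop("generation error: could not derive foreign homolog",
           call. = FALSE)
    })
    foreign <- do.call(rbind, rows)
  }

  # final uniqueness audit of all planted matures
  gs <- genome_set()
  bad <- vapply(matures, function(m) genome_pattern_count(m, gs) != 1L,
                logical(1))
  if (any(bad)) {
    stop("generation error: planted mature not unique in genome",
         call. = FALSE)
  }

  annotation <- data.frame(
    name = known$name, species = "hsa",
    mature_sequence = normalize_rna(known$sequence),
    chrom = known$chrom, start = known$start, end = known$end,
    strand = known$strand, stringsAsFactors = FALSE)
  if (!is.null(foreign)) annotation <- rbind(annotation, foreign)

  ids <- c(known$name, hp$hp_id)
  ratios <- resolve_ratios(ids, spec)

  truth <- list(
    known = cbind(known, ratio = unname(ratios[known$name])),
    hairpins = if (nrow(hp)) cbind(hp, ratio = unname(ratios[hp$hp_id]))
               else hp,
    decoys = decoys,
    ratios = ratios,
    true_de_set = names(ratios)[abs(log2(ratios)) > log2(2)]
  )
  mf_log("simulate_genome_and_annotation: %d chrom, %d known, %d hairpins, %d decoys, %d ncRNAs",
         spec$n_chromosomes, spec$n_known_mirnas, nrow(hp), nrow(decoys),
         length(ncrna))
  list(genome = genome, annotation = annotation, ncrna = ncrna,
       truth = truth)
}

draw_counts <- function(mu, dispersion) {
  if (dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  } else {
    round(mu)
  }
}

log_uniform <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

#' Simulate per-sample collapsed reads and the count table
#'
#' Per-miRNA baseline expression is drawn log-uniformly; the late-group
#' mean is the mid-group mean times the planted ratio; counts are
#' negative binomial around the means (deterministic at dispersion 0).
#' Per-sample sequencing-depth factors are drawn within +/-10% of
#' `depth_per_sample`. Besides known-miRNA reads, each sample carries
#' reads from novel hairpin matures, decoy loci, ncRNAs, plus a few
#' too-short (< 18 nt) and genome-unmatched reads so the whole QC
#' cascade is exercised. Reads are emitted in the `seq-<rank>_x<count>`
#' dialect, ranked by descending count within each sample.
#'
#' @param spec A [simulation_spec()].
#' @param sim Output of [simulate_genome_and_annotation()].
#' @return List with `reads_by_sample` (named list of read data
#'   frames), `table` (a [count_table()] of known miRNAs with
#'   genome-matched denominators), `novel_counts` (hairpin x sample
#'   matrix), and `truth` (per-sample totals, groups, per-entity
#'   counts).
#' @export
simulate_counts <- function(spec, sim) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed + 1L)
  n <- spec$n_samples_per_group
  samples <- c(paste0("mid_", seq_len(n)), paste0("late_", seq_len(n)))
  groups <- rep(c("mid", "late"), each = n)
  depth_factor <- stats::runif(2L * n, 0.9, 1.1)
  genome_set <- Biostrings::DNAStringSet(sim$genome)
  ratios <- sim$truth$ratios

  mu_for <- function(ids, baselines) {
    mu <- outer(baselines, depth_factor)
    late_cols <- which(groups == "late")
    mu[, late_cols] <- mu[, late_cols] * ratios[ids]
    dimnames(mu) <- list(ids, samples)
    mu
  }

  known_ids <- sim$truth$known$name
  known_seq <- normalize_rna(sim$truth$known$sequence)
  known_mu <- mu_for(known_ids, log_uniform(length(known_ids), 20, 2000))
  known_counts <- draw_counts(known_mu, spec$dispersion)

  hp <- sim$truth$hairpins
  novel_counts <- matrix(0, 0, 2L * n, dimnames = list(NULL, samples))
  if (nrow(hp)) {
    novel_mu <- mu_for(hp$hp_id, log_uniform(nrow(hp), 15, 400))
    novel_counts <- draw_counts(novel_mu, spec$dispersion)
  }

  decoys <- sim$truth$decoys
  decoy_reads <- character(0)
  if (nrow(decoys)) {
    decoy_reads <- vapply(seq_len(nrow(decoys)), function(i) {
      ch <- sim$genome[[decoys$chrom[i]]]
      for (try in 1:20) {
        off <- sample(0:(decoys$end[i] - decoys$start[i] - 22L), 1L)
        r <- substr(ch, decoys$start[i] + off + 1L, decoys$start[i] + off + 22L)
        if (!(normalize_rna(r) %in% known_seq) &&
            genome_pattern_count(r, genome_set) == 1L) return(r)
      }
      stop("generation error: could not pick decoy read", call. = FALSE)
    }, "")
    decoy_mu <- outer(log_uniform(nrow(decoys), 12, 100), depth_factor)
    dimnames(decoy_mu) <- list(decoys$decoy_id, samples)
    decoy_counts <- draw_counts(decoy_mu, spec$dispersion)
  } else decoy_counts <- matrix(0, 0, 2L * n, dimnames = list(NULL, samples))

  nc_reads <- character(0)
  if (length(sim$ncrna)) {
    nc_reads <- unlist(lapply(sim$ncrna, function(s) {
      offs <- sample(0:(nchar(s) - 22L), 2L)
      vapply(offs, function(o) substr(s, o + 1L, o + 22L), "")
    }), use.names = FALSE)
    nc_reads <- setdiff(unique(nc_reads), known_seq)
    nc_mu <- outer(log_uniform(length(nc_reads), 50, 500), depth_factor)
    dimnames(nc_mu) <- list(nc_reads, samples)
    nc_counts <- draw_counts(nc_mu, spec$dispersion)
  } else nc_counts <- matrix(0, 0, 2L * n, dimnames = list(NULL, samples))

  unaligned_reads <- character(0)
  while (length(unaligned_reads) < 3L) {
    r <- rand_seq(22L)
    if (genome_pattern_count(r, genome_set) == 0L) {
      unaligned_reads <- c(unaligned_reads, normalize_rna(r))
    }
  }
  unaligned_mu <- outer(log_uniform(3L, 10, 50), depth_factor)
  dimnames(unaligned_mu) <- list(unaligned_reads, samples)
  unaligned_counts <- draw_counts(unaligned_mu, spec$dispersion)

  short_reads <- vapply(1:3, function(i) {
    ch <- sample(names(sim$genome), 1L)
    pos <- sample(spec$chrom_length - 20L, 1L)
    substr(sim$genome[[ch]], pos, pos + 15L)
  }, "")
  short_mu <- outer(log_uniform(3L, 20, 100), depth_factor)
  dimnames(short_mu) <- list(normalize_rna(short_reads), samples)
  short_counts <- draw_counts(short_mu, spec$dispersion)

  # sequence-keyed count blocks (genome-matched vs not)
  rownames(known_counts) <- known_seq
  genome_matched_counts <- rbind(known_counts,
                                 if (nrow(hp)) {
                                   m <- novel_counts
                                   rownames(m) <- hp$mature_sequence
                                   m
                                 },
                                 if (nrow(decoys)) {
                                   m <- decoy_counts
                                   rownames(m) <- normalize_rna(decoy_reads)
                                   m
                                 },
                                 nc_counts)
  other_counts <- rbind(unaligned_counts, short_counts)
  per_sample_totals <- colSums(genome_matched_counts)

  reads_by_sample <- lapply(seq_along(samples), function(j) {
    all_counts <- c(genome_matched_counts[, j], other_counts[, j])
    all_counts <- all_counts[all_counts > 0]
    agg <- tapply(all_counts, names(all_counts), sum)
    ord <- order(-agg, names(agg))
    data.frame(
      read_id = sprintf("seq-%d_x%d", seq_along(ord), as.integer(agg[ord])),
      sequence = names(agg)[ord], count = as.integer(agg[ord]),
      stringsAsFactors = FALSE)
  })
  names(reads_by_sample) <- samples

  counts_known <- known_counts
  rownames(counts_known) <- known_ids
  table <- count_table(counts_known, groups, per_sample_totals)

  truth <- list(per_sample_totals = per_sample_totals,
                groups = stats::setNames(groups, samples),
                hairpin_total_counts = if (nrow(hp))
                  stats::setNames(rowSums(novel_counts), hp$hp_id)
                else stats::setNames(numeric(0), character(0)),
                decoy_reads = decoy_reads)
  mf_log("simulate_counts: %d samples, totals %s", length(samples),
         paste(round(per_sample_totals), collapse = "/"))
  list(reads_by_sample = reads_by_sample, table = table,
       novel_counts = novel_counts, truth = truth)
}

PATHWAY_GENES <- c("TGFB2", "TGFB3", "TGFBR1", "TGFBR2",
                   "SMAD2", "SMAD3", "SMAD4", "SAR1A")

#' Simulate 3'UTRs with planted seed sites and a pathway gene set
#'
#' Each planted (miRNA, gene) pair places exactly one reverse complement
#' of the miRNA's seed into that gene's UTR at a recorded offset.
#' Non-target UTR sequence is screened to contain no seed complement of
#' any annotated miRNA or novel hairpin mature, so the target-prediction
#' stage sees exactly the planted sites. With automatic planting, most
#' differentially expressed novel hairpins target 2 pathway genes and
#' one targets exactly 1 (a below-threshold boundary case); some known
#' miRNAs are planted likewise.
#'
#' @param spec A [simulation_spec()].
#' @param sim Output of [simulate_genome_and_annotation()].
#' @return List with `utrs` (named RNA character vector),
#'   `pathway_genes` (character vector) and `truth` (`target_sites`
#'   data frame of planted sites with offsets, `pathway_related` ids).
#' @export
simulate_utrs_and_pathway <- function(spec, sim) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed + 2L)
  cfg <- pipeline_config()
  genes <- c(PATHWAY_GENES,
             sprintf("GENE%03d", seq_len(spec$n_utrs - length(PATHWAY_GENES))))
  hp <- sim$truth$hairpins
  mirna_seq <- c(stats::setNames(sim$annotation$mature_sequence,
                                 sim$annotation$name),
                 if (nrow(hp)) stats::setNames(hp$mature_sequence, hp$hp_id))
  seeds <- extract_seed(mirna_seq, cfg)
  screen_rc <- unique(revcomp_rna(seeds))

  planted <- spec$planted_sites
  if (is.null(planted)) {
    planted <- list()
    ratios <- sim$truth$ratios
    de_hp <- intersect(hp$hp_id, sim$truth$true_de_set)
    n_rel <- ceiling(0.7 * length(de_hp))
    for (id in de_hp[seq_len(n_rel)]) {
      planted[[id]] <- sample(PATHWAY_GENES, 2L)
    }
    if (length(de_hp) > n_rel) {
      planted[[de_hp[n_rel + 1L]]] <- sample(PATHWAY_GENES, 1L)
    }
    de_known <- intersect(sim$truth$known$name, sim$truth$true_de_set)
    n_rel_known <- ceiling(0.4 * length(de_known))
    for (id in de_known[seq_len(n_rel_known)]) {
      planted[[id]] <- sample(PATHWAY_GENES, sample(2:3, 1L))
    }
    if (length(de_known) > n_rel_known) {
      planted[[de_known[n_rel_known + 1L]]] <- sample(PATHWAY_GENES, 1L)
    }
    # scatter a few non-pathway sites
    others <- setdiff(genes, PATHWAY_GENES)
    for (id in sample(names(mirna_seq), min(5L, length(mirna_seq)))) {
      planted[[id]] <- unique(c(planted[[id]], sample(others, 1L)))
    }
  }
  bad_ids <- setdiff(names(planted), names(mirna_seq))
  if (length(bad_ids)) {
    stop("validation error: planted_sites refers to unknown miRNA(s): ",
         paste(bad_ids, collapse = ", "), call. = FALSE)
  }

  pairs <- do.call(rbind, lapply(names(planted), function(id) {
    data.frame(mirna_id = id, gene_id = planted[[id]],
               stringsAsFactors = FALSE)
  }))

  utr_len <- 200L
  utrs <- character(0)
  site_rows <- list()
  for (g in genes) {
    gp <- if (!is.null(pairs)) pairs[pairs$gene_id == g, , drop = FALSE]
          else data.frame(mirna_id = character(0), gene_id = character(0))
    g_rc <- revcomp_rna(seeds[gp$mirna_id])
    want <- table(g_rc)  # per unique site sequence
    done <- FALSE
    for (try in 1:200) {
      base <- normalize_rna(rand_seq(utr_len))
      if (any(vapply(screen_rc, function(s) grepl(s, base, fixed = TRUE),
                     logical(1)))) next
      offs <- integer(0)
      if (nrow(gp)) {
        pool <- seq(5L, utr_len - 15L, by = 12L)
        offs <- sample(pool, nrow(gp))
        u <- base
        for (t in seq_len(nrow(gp))) {
          substr(u, offs[t] + 1L, offs[t] + nchar(g_rc[t])) <- g_rc[t]
        }
      } else u <- base
      counts <- vapply(screen_rc, count_occurrences, integer(1), subject = u)
      expect <- stats::setNames(rep(0L, length(screen_rc)), screen_rc)
      expect[names(want)] <- as.integer(want)
      if (all(counts == expect)) {
        utrs[g] <- u
        if (nrow(gp)) {
          site_rows[[g]] <- data.frame(
            mirna_id = gp$mirna_id, gene_id = g, utr_offset = offs,
            site_sequence = g_rc, stringsAsFactors = FALSE)
        }
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("generation error: could not screen UTR for gene ", g,
           call. = FALSE)
    }
  }
  target_sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               utr_offset = integer(0), site_sequence = character(0),
               stringsAsFactors = FALSE)
  rownames(target_sites) <- NULL
  n_pw <- vapply(names(planted), function(id)
    length(intersect(planted[[id]], PATHWAY_GENES)), integer(1))
  truth <- list(target_sites = target_sites,
                planted_sites = planted,
                pathway_related = names(planted)[n_pw >= 2L])
  mf_log("simulate_utrs_and_pathway: %d UTRs, %d planted sites, %d pathway-related miRNAs",
         length(utrs), nrow(target_sites), length(truth$pathway_related))
  list(utrs = utrs, pathway_genes = PATHWAY_GENES, truth = truth)
}

#' Simulate a qPCR Ct table consistent with planted expression ratios
#'
#' For each miRNA the late-group Ct shifts by `-log2(ratio)` relative to
#' the mid group (the exact 2^-ddCt relationship) plus Gaussian
#' sample-level noise; the U6 reference is flat across samples up to
#' replicate noise.
#'
#' @param ratios Named numeric vector of true late/mid ratios.
#' @param n_samples_per_group Samples per group (default 3).
#' @param n_replicates Technical replicates per sample (default 3).
#' @param sample_sd Sample-level Ct noise (default 0.15 cycles).
#' @param replicate_sd Replicate-level Ct noise (default 0.1 cycles).
#' @param rng_seed Integer seed.
#' @return A Ct measurement data frame (see [ddct()]).
#' @export
simulate_ct_table <- function(ratios, n_samples_per_group = 3L,
                              n_replicates = 3L, sample_sd = 0.15,
                              replicate_sd = 0.1, rng_seed = 1L) {
  set.seed(rng_seed)
  n <- n_samples_per_group
  samples <- c(paste0("mid_", seq_len(n)), paste0("late_", seq_len(n)))
  groups <- rep(c("mid", "late"), each = n)
  rows <- list()
  for (tg in c(names(ratios), "U6")) {
    base_mid <- if (tg == "U6") 20 else stats::runif(1, 23, 28)
    shift <- if (tg == "U6") 0 else -log2(ratios[[tg]])
    for (s in seq_along(samples)) {
      mu <- base_mid + if (groups[s] == "late") shift else 0
      mu <- mu + if (tg == "U6") 0 else stats::rnorm(1, 0, sample_sd)
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = tg, sample_id = samples[s], group = groups[s],
          replicate = r, ct = mu + stats::rnorm(1, 0, replicate_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete study and optionally write it to disk
#'
#' Runs [simulate_genome_and_annotation()], [simulate_counts()],
#' [simulate_utrs_and_pathway()] and [simulate_ct_table()] under one
#' seed. With `outdir`, writes `genome.fa`, `known.tsv`, `ncrna.fa`,
#' `sample_<group>_<i>.fa`, `utrs.fa`, `pathway.txt`, `counts.tsv`,
#' `groups.tsv`, `ct.tsv` and `truth.json`. Outputs are byte-identical
#' under a fixed `rng_seed`.
#'
#' @param spec A [simulation_spec()].
#' @param outdir Output directory, or `NULL` for in-memory only.
#' @return List with components `genome_ann`, `counts`, `utr`,
#'   `ct_table` and `spec` (invisibly when writing).
#' @export
simulate_dataset <- function(spec = simulation_spec(), outdir = NULL) {
  ga <- simulate_genome_and_annotation(spec)
  cnt <- simulate_counts(spec, ga)
  utr <- simulate_utrs_and_pathway(spec, ga)
  de_ids <- ga$truth$true_de_set
  qpcr_ids <- utils::head(de_ids, 10L)
  ct_tab <- simulate_ct_table(ga$truth$ratios[qpcr_ids],
                              n_samples_per_group = spec$n_samples_per_group,
                              rng_seed = spec$rng_seed + 3L)
  out <- list(genome_ann = ga, counts = cnt, utr = utr, ct_table = ct_tab,
              spec = spec)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ga$genome, file.path(outdir, "genome.fa"))
    write_annotation_table(ga$annotation, file.path(outdir, "known.tsv"))
    write_fasta(rna_to_dna(ga$ncrna), file.path(outdir, "ncrna.fa"))
    for (s in names(cnt$reads_by_sample)) {
      write_count_fasta(cnt$reads_by_sample[[s]],
                        file.path(outdir, paste0("sample_", s, ".fa")))
    }
    write_fasta(rna_to_dna(utr$utrs), file.path(outdir, "utrs.fa"))
    writeLines(utr$pathway_genes, file.path(outdir, "pathway.txt"))
    utils::write.table(
      data.frame(mirna_id = rownames(cnt$table$counts), cnt$table$counts,
                 check.names = FALSE),
      file.path(outdir, "counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = colnames(cnt$table$counts),
                 group = cnt$table$groups,
                 denominator = cnt$table$denominators),
      file.path(outdir, "groups.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(ct_tab, file.path(outdir, "ct.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth <- list(genome = ga$truth, counts = cnt$truth, utr = utr$truth)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
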