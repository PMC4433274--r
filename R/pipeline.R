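# End-to-end convenience wrapper: simulate a study (or take one
# pre-simulated), then run classification, differential expression,
# candidate discovery, conservation, target/pathway analysis,
# proximity clustering and qPCR cross-validation.

#' Run the full analysis pipeline on a simulated study
#'
#' @param spec A [simulation_spec()].
#' @param config A [pipeline_config()].
#' @param sim Optional pre-built result of [simulate_dataset()] (so the
#'   same data can be analysed under several configurations).
#' @return A list with the simulated data (`sim`), per-sample QC
#'   cascades (`cascades`), the recomputed known+novel count table
#'   (`table`), DE calls with origin (`de`), retained candidates
#'   (`candidates`), conservation hits (`conservation`), target sites
#'   (`sites`), pathway assessments (`assessments`) and summary
#'   (`pathway`), genomic clusters (`clusters`) and their DE
#'   concordance (`concordance`), qPCR relative expression (`qpcr`),
#'   the NGS-vs-qPCR correlation (`correlation`), and discovery
#'   performance against ground truth (`discovery_eval`).
#' @export
run_pipeline <- function(spec = simulation_spec(),
                         config = pipeline_config(), sim = NULL) {
  if (is.null(sim)) sim <- simulate_dataset(spec)
  ga <- sim$genome_ann; cnt <- sim$counts; utr <- sim$utr
  genome <- ga$genome
  panel <- ga$annotation
  samples <- names(cnt$reads_by_sample)
  groups <- unname(cnt$truth$groups[samples])

  # per-sample QC classification
  cls <- lapply(cnt$reads_by_sample, function(r)
    classify_reads(r, genome, panel, ga$ncrna, config))
  cascades <- lapply(cls, `[[`, "cascade")
  denominators <- vapply(cascades, `[[`, numeric(1), "genome_matched")

  # known-miRNA counts recomputed from the classification
  known_ids <- panel$name[!is.na(panel$chrom)]
  known_mat <- vapply(cls, function(x) {
    k <- x$classified[x$classified$category == "known_mirna", , drop = FALSE]
    agg <- tapply(k$count, k$matched_name, sum)
    out <- stats::setNames(rep(0, length(known_ids)), known_ids)
    out[names(agg)] <- agg
    out
  }, numeric(length(known_ids)))

  # combined reads across samples for discovery
  all_reads <- do.call(rbind, cnt$reads_by_sample)
  agg <- tapply(all_reads$count, all_reads$sequence, sum)
  combined <- data.frame(read_id = sprintf("combined-%d", seq_along(agg)),
                         sequence = names(agg), count = as.integer(agg),
                         stringsAsFactors = FALSE)
  combined_cls <- classify_reads(combined, genome, panel, ga$ncrna, config)

  per_sample_counts <- vapply(cnt$reads_by_sample, function(r) {
    out <- stats::setNames(rep(0, nrow(combined)), combined$sequence)
    out[r$sequence] <- r$count
    out
  }, numeric(nrow(combined)))
  rownames(per_sample_counts) <- combined$sequence

  candidates <- discover_candidates(combined_cls$classified, genome, config,
                                    per_sample_counts = per_sample_counts)

  novel_mat <- matrix(0, 0, length(samples),
                      dimnames = list(NULL, samples))
  if (nrow(candidates)) {
    cc <- as.matrix(candidates[, paste0("count_", samples), drop = FALSE])
    rownames(cc) <- candidates$candidate_id
    colnames(cc) <- samples
    novel_mat <- cc
  }
  table <- count_table(rbind(known_mat, novel_mat), groups, denominators)
  de <- call_de(table, config)
  de$origin <- ifelse(de$mirna_id %in% known_ids, "known", "novel")

  conservation <- if (nrow(candidates))
    classify_conservation(candidates, panel, config)
  else NULL

  # target prediction for differentially expressed miRNAs
  de_ids <- de$mirna_id[de$differential]
  mirnas_t <- rbind(
    data.frame(mirna_id = intersect(de_ids, known_ids),
               mature_sequence = panel$mature_sequence[
                 match(intersect(de_ids, known_ids), panel$name)],
               stringsAsFactors = FALSE),
    data.frame(mirna_id = intersect(de_ids, candidates$candidate_id),
               mature_sequence = candidates$mature_sequence[
                 match(intersect(de_ids, candidates$candidate_id),
                       candidates$candidate_id)],
               stringsAsFactors = FALSE))
  sites <- predict_targets(mirnas_t, utr$utrs, config)
  assessments <- assess_pathway(sites, utr$pathway_genes, config,
                                mirna_ids = mirnas_t$mirna_id)
  pathway <- pathway_summary(assessments, de)

  # proximity clustering of DE known loci plus candidate precursor loci
  loci <- rbind(
    data.frame(mirna_id = intersect(de_ids, known_ids),
               chrom = panel$chrom[match(intersect(de_ids, known_ids),
                                         panel$name)],
               start = panel$start[match(intersect(de_ids, known_ids),
                                         panel$name)],
               end = panel$end[match(intersect(de_ids, known_ids),
                                     panel$name)],
               strand = panel$strand[match(intersect(de_ids, known_ids),
                                           panel$name)],
               stringsAsFactors = FALSE),
    if (nrow(candidates))
      data.frame(mirna_id = candidates$candidate_id,
                 chrom = candidates$chrom, start = candidates$start,
                 end = candidates$end, strand = candidates$strand,
                 stringsAsFactors = FALSE)
    else NULL)
  clusters <- cluster_loci(loci, gap = config$cluster_gap)
  concordance <- cluster_de_concordance(clusters, de)

  # qPCR cross-validation: map truth ids to analysis ids
  qpcr <- ddct(sim$ct_table)
  hp <- ga$truth$hairpins
  analysis_id <- vapply(qpcr$mirna_id, function(id) {
    if (id %in% known_ids) return(id)
    if (id %in% hp$hp_id) {
      mat <- hp$mature_sequence[hp$hp_id == id]
      hit <- candidates$candidate_id[candidates$mature_sequence == mat]
      if (length(hit)) return(hit[1L])
    }
    NA_character_
  }, "")
  mapped <- !is.na(analysis_id)
  ngs_ratios <- stats::setNames(
    de$ratio[match(analysis_id[mapped], de$mirna_id)],
    qpcr$mirna_id[mapped])
  qpcr_ratios <- stats::setNames(qpcr$ratio, qpcr$mirna_id)[mapped]
  correlation <- tryCatch(
    ngs_qpcr_correlation(ngs_ratios, qpcr_ratios),
    error = function(e) NULL)

  discovery_eval <- evaluate_discovery(candidates, ga$truth, cnt$truth,
                                       config)
  list(sim = sim, cascades = cascades, table = table, de = de,
       candidates = candidates, conservation = conservation,
       sites = sites, assessments = assessments, pathway = pathway,
       clusters = clusters, concordance = concordance, qpcr = qpcr,
       correlation = correlation, discovery_eval = discovery_eval)
}

#' Score candidate discovery against simulation ground truth
#'
#' Recovery is the fraction of planted hairpins with at least
#' `min_candidate_count` total reads whose mature sequence appears among
#' the retained candidates; decoy rejection is the fraction of decoy
#' loci contributing no retained candidate.
#'
#' @param candidates Output of [discover_candidates()].
#' @param truth_genome `truth` component of
#'   [simulate_genome_and_annotation()].
#' @param truth_counts `truth` component of [simulate_counts()].
#' @param config A [pipeline_config()].
#' @return List with `n_eligible_hairpins`, `n_recovered`, `recovery`,
#'   `n_decoys`, `n_decoys_rejected`, `decoy_rejection`.
#' @export
evaluate_discovery <- function(candidates, truth_genome, truth_counts,
                               config = pipeline_config()) {
  hp <- truth_genome$hairpins
  eligible <- hp$hp_id[truth_counts$hairpin_total_counts[hp$hp_id] >=
                         config$min_candidate_count]
  recovered <- hp$hp_id[hp$mature_sequence %in% candidates$mature_sequence &
                          hp$hp_id %in% eligible]
  member_seqs <- unique(unlist(candidates$member_sequences))
  decoy_reads <- normalize_rna(truth_counts$decoy_reads)
  n_decoys <- length(decoy_reads)
  n_rejected <- sum(!decoy_reads %in% member_seqs)
  list(
    n_eligible_hairpins = length(eligible),
    n_recovered = length(recovered),
    recovery = if (length(eligible)) length(recovered) / length(eligible)
               else NA_real_,
    n_decoys = n_decoys,
    n_decoys_rejected = n_rejected,
    decoy_rejection = if (n_decoys) n_rejected / n_decoys else NA_real_
  )
}
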