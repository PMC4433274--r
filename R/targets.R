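# Seed-complement target prediction in 3'UTRs and pathway-relatedness
# classification: a gene is a predicted target when the reverse
# complement of the miRNA seed occurs exactly in its 3'UTR; a miRNA is
# pathway-related when it targets at least `min_pathway_targets`
# distinct genes of the pathway set.

#' Predict seed-complement target sites in 3'UTRs
#'
#' Reports every exact (possibly overlapping) occurrence of the reverse
#' complement of each miRNA's seed in each UTR. A gene is targeted iff
#' it has at least one site.
#'
#' @param mirnas Data frame with `mirna_id` and `mature_sequence` (the
#'   seed is extracted per `config`), or columns `mirna_id` and `seed`.
#' @param utrs Named character vector mapping gene id to UTR sequence
#'   (DNA or RNA; normalized to RNA).
#' @param config A [pipeline_config()].
#' @return Data frame with `mirna_id`, `gene_id`, `utr_offset` (0-based
#'   site start) and `site_sequence` (the seed's reverse complement).
#' @export
predict_targets <- function(mirnas, utrs, config = pipeline_config()) {
  out <- data.frame(mirna_id = character(0), gene_id = character(0),
                    utr_offset = integer(0), site_sequence = character(0),
                    stringsAsFactors = FALSE)
  if (length(utrs) == 0L) {
    warning("predict_targets: empty UTR set")
    return(out)
  }
  utrs <- normalize_rna(utrs)
  seeds <- if ("seed" %in% names(mirnas)) normalize_rna(mirnas$seed)
           else extract_seed(mirnas$mature_sequence, config)
  sites <- revcomp_rna(seeds)
  subjects <- lapply(utrs, Biostrings::RNAString)
  rows <- list()
  for (i in seq_along(sites)) {
    pat <- Biostrings::RNAString(sites[i])
    for (g in names(subjects)) {
      m <- Biostrings::matchPattern(pat, subjects[[g]])
      starts <- Biostrings::start(m)
      if (length(starts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mirnas$mirna_id[i], gene_id = g,
          utr_offset = starts - 1L, site_sequence = sites[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mf_log("predict_targets: %d miRNAs x %d UTRs -> %d sites",
         nrow(mirnas), length(utrs), nrow(out))
  out
}

#' Classify pathway relatedness of miRNAs from their target sites
#'
#' Per miRNA, counts the distinct pathway genes with at least one seed
#' site; `related` is true iff that count reaches
#' `min_pathway_targets`. Overlapping or repeated sites in one gene
#' count once.
#'
#' @param sites Data frame from [predict_targets()].
#' @param pathway_genes Character vector of primary pathway gene ids.
#' @param config A [pipeline_config()].
#' @param mirna_ids Optional character vector of miRNAs to assess
#'   (defaults to those present in `sites`); miRNAs without sites get
#'   `n_targeted = 0`.
#' @param pathway_name Label carried through to the output.
#' @return Data frame with `mirna_id`, `pathway_name`,
#'   `targeted_primary_genes` (comma-separated), `n_targeted`,
#'   `related`.
#' @export
assess_pathway <- function(sites, pathway_genes, config = pipeline_config(),
                           mirna_ids = NULL, pathway_name = "pathway") {
  if (is.null(mirna_ids)) mirna_ids <- unique(sites$mirna_id)
  rows <- lapply(mirna_ids, function(id) {
    genes <- sort(unique(sites$gene_id[sites$mirna_id == id &
                                       sites$gene_id %in% pathway_genes]))
    data.frame(mirna_id = id, pathway_name = pathway_name,
               targeted_primary_genes = paste(genes, collapse = ","),
               n_targeted = length(genes),
               related = length(genes) >= config$min_pathway_targets,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), pathway_name = character(0),
               targeted_primary_genes = character(0),
               n_targeted = integer(0), related = logical(0),
               stringsAsFactors = FALSE)
  mf_log("assess_pathway: %d miRNAs assessed, %d related",
         nrow(out), sum(out$related))
  out
}

#' Summarize pathway-related miRNAs by origin and direction
#'
#' Cross-tabulates pathway-related, differentially expressed miRNAs by
#' origin (`known`/`novel`) and direction (`up`/`down`), and reports the
#' share of related novel candidates among all differentially expressed
#' novel candidates plus the share of up-regulated miRNAs among all
#' differentially expressed ones (both half-up, 2 decimals).
#'
#' @param assessments Data frame from [assess_pathway()].
#' @param de_calls Data frame from [call_de()] with an added `origin`
#'   column (`"known"` or `"novel"`). Assessed miRNAs missing from
#'   `de_calls` are dropped with a warning.
#' @return A list with `cells` (origin x direction counts of related,
#'   differential miRNAs), `n_related`, `n_de`, `n_de_novel`,
#'   `n_related_novel`, `pct_related_novel`, `n_de_up`,
#'   `pct_up_regulated`.
#' @export
pathway_summary <- function(assessments, de_calls) {
  stopifnot(all(c("mirna_id", "direction", "differential", "origin")
                %in% names(de_calls)))
  missing <- setdiff(assessments$mirna_id, de_calls$mirna_id)
  if (length(missing)) {
    warning("pathway_summary: ", length(missing),
            " assessed miRNA(s) missing from DE calls; excluded")
    assessments <- assessments[!assessments$mirna_id %in% missing, ,
                               drop = FALSE]
  }
  de <- de_calls[de_calls$differential, , drop = FALSE]
  related_ids <- assessments$mirna_id[assessments$related]
  rel <- de[de$mirna_id %in% related_ids, , drop = FALSE]
  cells <- table(factor(rel$origin, levels = c("known", "novel")),
                 factor(rel$direction, levels = c("up", "down")))
  n_de_novel <- sum(de$origin == "novel")
  n_related_novel <- sum(rel$origin == "novel")
  n_de_up <- sum(de$direction == "up")
  list(
    cells = cells,
    n_related = nrow(rel),
    n_de = nrow(de),
    n_de_novel = n_de_novel,
    n_related_novel = n_related_novel,
    pct_related_novel = if (n_de_novel > 0)
      percent(n_related_novel, n_de_novel) else NA_real_,
    n_de_up = n_de_up,
    pct_up_regulated = if (nrow(de) > 0)
      percent(n_de_up, nrow(de)) else NA_real_
  )
}
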