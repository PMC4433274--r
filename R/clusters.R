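# Genomic proximity clustering of miRNA loci: single-linkage chaining
# on each chromosome, joining consecutive loci whose end-to-start gap is
# at most `gap` bases. Strand is ignored. Singletons are dropped.

#' Cluster miRNA loci by genomic proximity
#'
#' Loci are sorted by start within each chromosome and chained: a locus
#' joins the open cluster iff `max(0, start - max_end_so_far) <= gap`.
#' Clusters with fewer than 2 members are dropped.
#'
#' @param loci Data frame with `mirna_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`.
#' @param gap Maximum inter-locus gap in bases (default 10000).
#' @return A list of class `genomic_clusters`: `members` (one row per
#'   clustered locus with its `cluster_id`) and `clusters` (per-cluster
#'   `chrom`, `n_members`, `span` from first start to last end, and
#'   `max_gap_used` = `gap`).
#' @export
cluster_loci <- function(loci, gap = 10000L) {
  stopifnot(all(c("mirna_id", "chrom", "start", "end") %in% names(loci)))
  if (any(loci$start >= loci$end)) {
    stop("validation error: locus start must be < end", call. = FALSE)
  }
  if (!"strand" %in% names(loci)) loci$strand <- NA_character_
  loci <- loci[order(loci$chrom, loci$start, loci$end, loci$mirna_id), ,
               drop = FALSE]
  cid <- integer(nrow(loci))
  cur <- 0L; max_end <- -Inf; cur_chrom <- ""
  for (t in seq_len(nrow(loci))) {
    if (loci$chrom[t] != cur_chrom ||
        max(0, loci$start[t] - max_end) > gap) {
      cur <- cur + 1L
      cur_chrom <- loci$chrom[t]
      max_end <- loci$end[t]
    } else {
      max_end <- max(max_end, loci$end[t])
    }
    cid[t] <- cur
  }
  loci$cluster_id <- cid
  sizes <- table(cid)
  keep_ids <- as.integer(names(sizes)[sizes >= 2L])
  members <- loci[loci$cluster_id %in% keep_ids, , drop = FALSE]
  # renumber clusters 1..k in genomic order
  members$cluster_id <- match(members$cluster_id, keep_ids)
  rownames(members) <- NULL
  clusters <- do.call(rbind, lapply(seq_along(keep_ids), function(k) {
    m <- members[members$cluster_id == k, , drop = FALSE]
    data.frame(cluster_id = k, chrom = m$chrom[1L],
               n_members = nrow(m),
               span = max(m$end) - min(m$start),
               max_gap_used = as.integer(gap),
               members = paste(m$mirna_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = integer(0), chrom = character(0),
                           n_members = integer(0), span = integer(0),
                           max_gap_used = integer(0), members = character(0),
                           stringsAsFactors = FALSE)
  }
  mf_log("cluster_loci: %d loci -> %d clusters (%d clustered loci) at gap %d",
         nrow(loci), nrow(clusters), nrow(members), as.integer(gap))
  structure(list(members = members, clusters = clusters, gap = as.integer(gap)),
            class = "genomic_clusters")
}

#' Direction concordance of differential expression within clusters
#'
#' Per cluster, lists the member directions and flags the cluster
#' concordant when all members share one direction among up/down. A
#' member missing from the DE calls gets direction `"none"` and is
#' tolerated (at most one missing member) when all remaining members
#' agree.
#'
#' @param clusters A [cluster_loci()] result.
#' @param de_calls Data frame from [call_de()].
#' @return Data frame with `cluster_id`, `chrom`, `n_members`,
#'   `directions` (comma-separated), `n_missing`, `concordant`.
#' @export
cluster_de_concordance <- function(clusters, de_calls) {
  stopifnot(inherits(clusters, "genomic_clusters"))
  members <- clusters$members
  out <- lapply(unique(members$cluster_id), function(k) {
    m <- members[members$cluster_id == k, , drop = FALSE]
    idx <- match(m$mirna_id, de_calls$mirna_id)
    missing <- is.na(idx)
    if (any(missing)) {
      mf_log("cluster_de_concordance: cluster %d member(s) without DE call: %s",
             k, paste(m$mirna_id[missing], collapse = ","))
    }
    dirs <- ifelse(missing, "none", de_calls$direction[idx])
    present <- dirs[!missing]
    concordant <- sum(missing) <= 1L && length(present) >= 1L &&
      length(unique(present)) == 1L && present[1L] %in% c("up", "down")
    data.frame(cluster_id = k, chrom = m$chrom[1L], n_members = nrow(m),
               directions = paste(dirs, collapse = ","),
               n_missing = sum(missing), concordant = concordant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(cluster_id = integer(0), chrom = character(0),
                      n_members = integer(0), directions = character(0),
                      n_missing = integer(0), concordant = logical(0),
                      stringsAsFactors = FALSE)
  }
  out
}
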