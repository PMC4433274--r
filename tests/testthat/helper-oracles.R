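# Independent brute-force oracles used to validate the package's
# algorithmic primitives on small instances. These deliberately use
# naive enumeration, not the implementations under test.

options(mirflow.verbose = FALSE)

# Maximum total pair weight over ALL nested structures, by unmemoized
# leftmost-position enumeration (exhaustive for small n).
oracle_fold_weight <- function(sequence, min_loop = 3L) {
  ch <- strsplit(normalize_rna(sequence), "")[[1]]
  w <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) 3 else if (key %in% c("AU", "UA")) 2
    else if (key %in% c("GU", "UG")) 1 else 0
  }
  rec <- function(i, j) {
    if (i >= j) return(0)
    best <- rec(i + 1L, j)          # position i unpaired
    ks <- seq_len(j)
    ks <- ks[ks >= i + min_loop + 1L]
    for (k in ks) {
      wk <- w(ch[i], ch[k])
      if (wk > 0) best <- max(best, wk + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(ch))
}

# Maximum number of identical aligned characters with free gaps =
# longest common subsequence, by exhaustive subsequence enumeration
# (feasible for nchar(a) <= 10).
oracle_max_matches <- function(a, b) {
  xa <- strsplit(a, "")[[1]]; xb <- strsplit(b, "")[[1]]
  is_subseq <- function(s, y) {
    j <- 1L
    for (c in y) {
      if (j <= length(s) && s[j] == c) j <- j + 1L
    }
    j > length(s)
  }
  best <- 0L
  for (mask in 0:(2^length(xa) - 1L)) {
    s <- xa[bitwAnd(mask, 2^(seq_along(xa) - 1L)) > 0]
    if (length(s) > best && is_subseq(s, xb)) best <- length(s)
  }
  best
}

# Naive O(n*m) substring scan of a read (RNA) against DNA chromosomes,
# both strands; returns 0-based half-open hits.
oracle_genome_hits <- function(seq_rna, genome) {
  d <- chartr("U", "T", toupper(seq_rna))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", d), "")[[1]]), collapse = "")
  k <- nchar(d)
  out <- list()
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    for (i in seq_len(max(0L, nchar(g) - k + 1L))) {
      win <- substr(g, i, i + k - 1L)
      if (win == d) out[[length(out) + 1L]] <-
          data.frame(chrom = chrom, start = i - 1L, end = i - 1L + k,
                     strand = "+", stringsAsFactors = FALSE)
      if (win == rc) out[[length(out) + 1L]] <-
          data.frame(chrom = chrom, start = i - 1L, end = i - 1L + k,
                     strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Naive cascade classification of one read.
oracle_classify <- function(seq_rna, genome, panel_seqs, ncrna,
                            min_read_length = 18L) {
  if (nchar(seq_rna) < min_read_length) return("too_short")
  hits <- oracle_genome_hits(seq_rna, genome)
  if (nrow(hits) == 0L) return("unaligned")
  if (seq_rna %in% panel_seqs) return("known_mirna")
  for (s in ncrna) {
    if (grepl(seq_rna, s, fixed = TRUE)) return("ncrna")
  }
  "unannotated"
}

# Naive scan for all (overlapping) occurrences of `site` in `utr`
# (0-based offsets).
oracle_site_offsets <- function(site, utr) {
  k <- nchar(site); n <- nchar(utr)
  offs <- integer(0)
  for (i in seq_len(max(0L, n - k + 1L))) {
    if (substr(utr, i, i + k - 1L) == site) offs <- c(offs, i - 1L)
  }
  offs
}

# Transitive closure of pairwise proximity (gap <= g, same chromosome):
# returns membership partition as a list of sorted id vectors, clusters
# of size >= 2 only.
oracle_cluster <- function(loci, gap) {
  n <- nrow(loci)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && loci$chrom[i] == loci$chrom[j]) {
      g <- max(0L, max(loci$start[i], loci$start[j]) -
                  min(loci$end[i], loci$end[j]))
      adj[i, j] <- g <= gap
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  parts <- split(loci$mirna_id, comp)
  parts <- parts[vapply(parts, length, integer(1)) >= 2L]
  unname(lapply(parts, sort))
}

# Random RNA string helper for property tests.
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Small, fast simulation spec used across tests; ... overrides defaults.
tiny_spec <- function(rng_seed = 1L, ...) {
  defaults <- list(n_chromosomes = 2L, chrom_length = 6000L,
                   n_known_mirnas = 12L, n_novel_hairpins = 3L,
                   n_decoy_loci = 3L, n_ncrnas = 2L,
                   n_foreign_homologs = 2L, n_utrs = 10L,
                   depth_per_sample = 5e4, rng_seed = rng_seed)
  do.call(simulation_spec, utils::modifyList(defaults, list(...)))
}
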