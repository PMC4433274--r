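test_that("maximum-weight folding handles canonical examples", {
  f <- fold_nussinov("GGGAAACCC", min_loop = 3)
  expect_equal(f$n_pairs, 3L)
  expect_equal(f$energy_score, -9)
  expect_equal(f$pairing, cbind(1:3, 9:7))
  expect_equal(f$dot_bracket, "(((...)))")

  f2 <- fold_nussinov("AAAAAA")
  expect_equal(f2$n_pairs, 0L)
  expect_equal(f2$energy_score, 0)

  expect_error(fold_nussinov("ACG"), "shorter than")
})

test_that("folding equals the exhaustive-enumeration oracle (n <= 14)", {
  set.seed(5150)
  for (i in 1:60) {
    s <- random_rna(sample(5:14, 1))
    f <- fold_nussinov(s)
    expect_equal(-f$energy_score, oracle_fold_weight(s), info = s)
  }
})

test_that("every fold is a valid nested structure", {
  set.seed(616)
  valid_pairs <- c("GC", "CG", "AU", "UA", "GU", "UG")
  for (i in 1:25) {
    s <- random_rna(sample(20:60, 1))
    f <- fold_nussinov(s)
    p <- f$pairing
    if (nrow(p) == 0) next
    ch <- strsplit(f$sequence, "")[[1]]
    expect_true(all(paste0(ch[p[, 1]], ch[p[, 2]]) %in% valid_pairs))
    expect_true(all(p[, 2] - p[, 1] > 3))          # loop >= min_loop
    expect_equal(anyDuplicated(as.vector(p)), 0L)  # each base once
    # no crossing pairs
    for (a in seq_len(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
      i1 <- p[a, 1]; j1 <- p[a, 2]; i2 <- p[b, 1]; j2 <- p[b, 2]
      crossing <- i1 < i2 && i2 < j1 && j1 < j2
      expect_false(crossing)
    }
    # determinism
    expect_identical(f$dot_bracket, fold_nussinov(s)$dot_bracket)
  }
})

test_that("constructed stem-loops pass and loop-spanning matures fail", {
  set.seed(99)
  arm <- "GCAUCGGAUCCAGGAUUACGCA"
  prec <- paste0(arm, "AAUUAAUU",
                 as.character(Biostrings::reverseComplement(
                   Biostrings::RNAString(arm))))
  h <- assess_hairpin(prec, arm)
  expect_true(h$is_hairpin)
  expect_equal(h$mature_arm, "5p")
  expect_gte(h$mature_paired_fraction, 0.6)

  # mature straddling the terminal loop violates the arm criterion
  mid <- substr(prec, 15, 36)
  h2 <- assess_hairpin(prec, mid)
  expect_false(h2$is_hairpin)

  expect_error(assess_hairpin(prec, "ACGUACGUACGU"), "exactly once")
  expect_error(assess_hairpin(paste0(prec, prec), arm), "exactly once")
})

test_that("shuffling a hairpin destroys it almost always", {
  set.seed(2024)
  arm <- random_rna(22)
  prec <- paste0("AUGCAUGCAU", arm, "GCGAAAUU",
                 as.character(Biostrings::reverseComplement(
                   Biostrings::RNAString(arm))), "CCAAUUGGCC")
  expect_true(assess_hairpin(prec, arm)$is_hairpin)
  rejected <- 0L; tested <- 0L
  for (i in 1:100) {
    sh <- paste(sample(strsplit(prec, "")[[1]]), collapse = "")
    mat <- substr(sh, 11, 32)
    if (mirflow:::count_occurrences(mat, sh) != 1L) {
      rejected <- rejected + 1L   # no unique mature: cannot be a candidate
    } else if (!assess_hairpin(sh, mat)$is_hairpin) {
      rejected <- rejected + 1L
    }
    tested <- tested + 1L
  }
  expect_gte(rejected / tested, 0.9)
})

test_that("discovery applies the count filter and hairpin gate", {
  spec <- tiny_spec(rng_seed = 31)
  ga <- simulate_genome_and_annotation(spec)
  hp <- ga$truth$hairpins
  dec <- ga$truth$decoys
  cfg <- pipeline_config()
  # hand-built reads: hairpin 1 with 12 counts, hairpin 2 with 9,
  # decoy read with 50
  decoy_read <- normalize_rna(
    substr(ga$genome[[dec$chrom[1]]], dec$start[1] + 1, dec$start[1] + 22))
  reads <- data.frame(
    read_id = c("a", "b", "c"),
    sequence = c(hp$mature_sequence[1], hp$mature_sequence[2], decoy_read),
    count = c(12L, 9L, 50L), stringsAsFactors = FALSE)
  cls <- classify_reads(reads, ga$genome, ga$annotation, ga$ncrna, cfg)
  expect_true(all(cls$classified$category == "unannotated"))
  cand <- discover_candidates(cls$classified, ga$genome, cfg)
  expect_equal(cand$mature_sequence, hp$mature_sequence[1])
  expect_equal(cand$total_count, 12L)
  expect_match(cand$candidate_id, "^seq-1_x12$")

  # retention is monotone in count: more reads never cause rejection
  reads2 <- reads; reads2$count[1] <- 500L
  cls2 <- classify_reads(reads2, ga$genome, ga$annotation, ga$ncrna, cfg)
  cand2 <- discover_candidates(cls2$classified, ga$genome, cfg)
  expect_true(hp$mature_sequence[1] %in% cand2$mature_sequence)

  # the 9-count hairpin was dropped by the count filter, not the fold:
  # the pre-filter locus table shows it as a hairpin
  loci <- attr(cand, "loci")
  row9 <- loci[loci$mature_sequence == hp$mature_sequence[2], ]
  expect_true(row9$is_hairpin)
  expect_lt(row9$total_count, cfg$min_candidate_count)
})

test_that("candidate ids rank by descending total count", {
  spec <- tiny_spec(rng_seed = 44)
  ga <- simulate_genome_and_annotation(spec)
  hp <- ga$truth$hairpins
  reads <- data.frame(
    read_id = c("a", "b", "c"),
    sequence = hp$mature_sequence,
    count = c(15L, 400L, 40L), stringsAsFactors = FALSE)
  cfg <- pipeline_config()
  cls <- classify_reads(reads, ga$genome, ga$annotation, ga$ncrna, cfg)
  cand <- discover_candidates(cls$classified, ga$genome, cfg)
  expect_equal(cand$total_count, sort(cand$total_count, decreasing = TRUE))
  expect_equal(cand$candidate_id,
               sprintf("seq-%d_x%d", seq_len(nrow(cand)), cand$total_count))
})
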