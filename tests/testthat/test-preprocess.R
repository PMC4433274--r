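# A small hand-built reference: one chromosome carrying a known mature,
# an ncRNA and unique filler, searched by classify_reads.
make_toy_reference <- function() {
  mature <- "ACGGTTACGGATCCAGGTTACG"                    # 22 nt
  ncrna <- "TTGACCGGTTAACCGGATTACCGGTTAACCGTTGCACCAA"   # 40 nt
  filler1 <- "GATTACAGATTACAGGCCTTAAGGCCAACCGGAATT"
  filler2 <- "CCAATTGGACGTACGTAACCGGTTGGCCAATTGGAACC"
  genome <- c(chr1 = paste0(filler1, mature, filler2, ncrna, filler1))
  panel <- data.frame(name = "hsa-miR-toy", species = "hsa",
                      mature_sequence = normalize_rna(mature),
                      chrom = "chr1", start = 36L, end = 58L, strand = "+",
                      stringsAsFactors = FALSE)
  list(genome = genome, panel = panel,
       ncrna = c(nc1 = normalize_rna(ncrna)), mature = mature)
}

test_that("the printed QC totals reproduce the printed percentages", {
  f <- qc_fractions(99354224, 85252341, 74678115, 61587749)
  expect_identical(unname(f), c(85.81, 87.60, 82.47))
})

test_that("reads fall through the cascade in the documented order", {
  ref <- make_toy_reference()
  cfg <- pipeline_config()
  reads <- data.frame(
    read_id = paste0("r", 1:5),
    sequence = c(normalize_rna(ref$mature),                  # known
                 normalize_rna(substr(ref$ncrna[[1]], 3, 24)),  # ncRNA
                 normalize_rna(substr(ref$genome[[1]], 5, 26)), # unannotated
                 normalize_rna(substr(ref$genome[[1]], 5, 21)), # 17 nt
                 "UUUUUUUUUUUUUUUUUUUUUU"),                  # unaligned
    count = c(100L, 20L, 30L, 40L, 7L), stringsAsFactors = FALSE)
  res <- classify_reads(reads, ref$genome, ref$panel, ref$ncrna, cfg)
  expect_equal(res$classified$category,
               c("known_mirna", "ncrna", "unannotated", "too_short",
                 "unaligned"))
  expect_equal(res$classified$matched_name[1], "hsa-miR-toy")
  # 17-nt read is excluded before any genome accounting
  expect_equal(res$classified$n_hits[4], 0L)
  casc <- res$cascade
  expect_equal(casc$raw_reads, 197)
  expect_equal(casc$high_quality_reads, 157)     # raw - too_short
  expect_equal(casc$genome_matched, 150)         # known + ncrna + unannot
  expect_equal(casc$known_mirna_matched, 100)
  expect_equal(casc$ncrna_matched, 20)
  expect_equal(casc$remaining_for_discovery, 30)
  # partition property: categories sum to raw
  expect_equal(sum(res$classified$count), casc$raw_reads)
})

test_that("one internal mismatch demotes a read from known_mirna", {
  ref <- make_toy_reference()
  mutated <- normalize_rna(ref$mature)
  substr(mutated, 11, 11) <- ifelse(substr(mutated, 11, 11) == "A", "C", "A")
  reads <- data.frame(read_id = "m", sequence = mutated, count = 1L,
                      stringsAsFactors = FALSE)
  res <- classify_reads(reads, ref$genome, ref$panel, ref$ncrna,
                        pipeline_config())
  expect_false(res$classified$category == "known_mirna")
  expect_true(res$classified$category %in% c("unaligned", "unannotated"))
})

test_that("classification agrees with the naive substring-scan oracle", {
  set.seed(404)
  genome <- c(chrA = paste(sample(c("A", "C", "G", "T"), 1200, TRUE),
                           collapse = ""),
              chrB = paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                           collapse = ""))
  panel_seq <- normalize_rna(substr(genome[["chrA"]], 101, 122))
  panel <- data.frame(name = "hsa-miR-o1", species = "hsa",
                      mature_sequence = panel_seq, stringsAsFactors = FALSE)
  ncrna <- c(nc = normalize_rna(substr(genome[["chrB"]], 201, 260)))
  seqs <- c(
    vapply(1:20, function(i) {            # genome-derived reads
      ch <- sample(names(genome), 1)
      pos <- sample(nchar(genome[[ch]]) - 25, 1)
      normalize_rna(substr(genome[[ch]], pos, pos + sample(16:24, 1)))
    }, ""),
    vapply(1:20, function(i) random_rna(sample(16:24, 1)), ""),  # random
    panel_seq,
    normalize_rna(substr(ncrna[[1]], 10, 31)))
  reads <- data.frame(read_id = paste0("r", seq_along(seqs)),
                      sequence = seqs, count = 1L, stringsAsFactors = FALSE)
  res <- classify_reads(reads, genome, panel, ncrna, pipeline_config())
  for (i in seq_along(seqs)) {
    expect_equal(res$classified$category[i],
                 oracle_classify(seqs[i], genome, panel_seq, ncrna),
                 info = paste("read", i))
    # hits match the naive scan exactly (order-independent)
    got <- res$classified$genome_hits[[i]]
    want <- oracle_genome_hits(seqs[i], genome)
    key <- function(d) sort(paste(d$chrom, d$start, d$end, d$strand))
    expect_equal(key(got), key(want), info = paste("hits", i))
  }
})

test_that("raising the length cutoff never raises the high-quality tally", {
  ref <- make_toy_reference()
  set.seed(7)
  reads <- data.frame(
    read_id = paste0("r", 1:30),
    sequence = vapply(1:30, function(i) random_rna(sample(14:26, 1)), ""),
    count = sample(1:50, 30, TRUE), stringsAsFactors = FALSE)
  hq <- vapply(c(14L, 18L, 22L, 27L), function(L) {
    classify_reads(reads, ref$genome, ref$panel, ref$ncrna,
                   pipeline_config(min_read_length = L)
                   )$cascade$high_quality_reads
  }, numeric(1))
  expect_true(all(diff(hq) <= 0))
})

test_that("qc_report tabulates stages and enforces invariants", {
  casc <- qc_cascade(99354224, 85252341, 74678115, 61587749, 4335108,
                     8755258)
  rep <- qc_report(casc)
  expect_equal(rep$percent[rep$stage == "high_quality"], 85.81)
  expect_equal(rep$percent[rep$stage == "genome_matched"], 87.60)
  expect_equal(rep$percent[rep$stage == "known_mirna"], 82.47)
  # identity case: everything genome-matched
  casc2 <- qc_cascade(100, 80, 80, 50, 10, 20)
  expect_equal(qc_report(casc2)$percent[3], 100.00)
  # broken partitions are internal errors
  expect_error(qc_cascade(100, 80, 70, 50, 10, 20), "partition")
  expect_error(qc_cascade(100, 120, 70, 50, 10, 10), "monotone")
  expect_error(classify_reads(data.frame(read_id = "r", sequence = "ACGU",
                                         count = 1L),
                              character(0), data.frame(), character(0)),
               "empty genome")
})
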