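loci_df <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  names(d) <- c("mirna_id", "chrom", "start", "end")[seq_along(d)]
  d
}

test_that("the 10 kb rule joins near loci and splits far ones", {
  near <- loci_df(c("a", "b"), "chr1", c(1000L, 9000L), c(1022L, 9022L))
  cl <- cluster_loci(near, gap = 10000)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_members, 2L)
  expect_equal(cl$clusters$span, 9022L - 1000L)

  far <- loci_df(c("a", "b"), "chr1", c(1000L, 20000L), c(1022L, 20022L))
  expect_equal(nrow(cluster_loci(far, gap = 10000)$clusters), 0L)

  # gap is measured end-to-start; exactly the threshold still joins
  edge <- loci_df(c("a", "b"), "chr1", c(0L, 10022L), c(22L, 10044L))
  expect_equal(nrow(cluster_loci(edge, gap = 10000)$clusters), 1L)
  expect_equal(nrow(cluster_loci(edge, gap = 9999)$clusters), 0L)
})

test_that("six planted pairs on six chromosomes give six 2-clusters", {
  loci <- do.call(rbind, lapply(1:6, function(i) {
    loci_df(paste0(c("m", "n"), i), paste0("chr", i),
            c(5000L, 12000L), c(5022L, 12022L))
  }))
  cl <- cluster_loci(loci, gap = 10000)
  expect_equal(nrow(cl$clusters), 6L)
  expect_true(all(cl$clusters$n_members == 2L))
  expect_equal(sort(unique(cl$members$chrom)), paste0("chr", 1:6))
})

test_that("chaining equals the transitive-closure oracle and ignores order", {
  set.seed(77)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    loci <- data.frame(
      mirna_id = paste0("m", seq_len(n)),
      chrom = sample(paste0("chr", 1:3), n, TRUE),
      start = sample.int(50000L, n), stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(20:120, n, TRUE)
    gap <- sample(c(500L, 2000L, 10000L), 1)
    got <- cluster_loci(loci, gap = gap)
    parts <- lapply(split(got$members$mirna_id, got$members$cluster_id),
                    sort)
    key <- function(p) sort(vapply(p, paste, "", collapse = ","))
    expect_equal(key(unname(parts)), key(oracle_cluster(loci, gap)),
                 info = paste("case", i))
    # input order must not matter
    got2 <- cluster_loci(loci[sample(n), ], gap = gap)
    parts2 <- lapply(split(got2$members$mirna_id, got2$members$cluster_id),
                     sort)
    expect_equal(key(unname(parts2)), key(unname(parts)))
  }
})

test_that("chaining matches interval reduction from GenomicRanges", {
  set.seed(555)
  n <- 30L
  loci <- data.frame(
    mirna_id = paste0("m", seq_len(n)),
    chrom = sample(paste0("chr", 1:2), n, TRUE),
    start = sample.int(30000L, n), stringsAsFactors = FALSE)
  loci$end <- loci$start + 22L
  gap <- 3000L
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  parts <- split(loci$mirna_id[S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits))
  parts <- unname(lapply(parts[lengths(parts) >= 2L], sort))
  got <- cluster_loci(loci, gap = gap)
  mine <- unname(lapply(split(got$members$mirna_id, got$members$cluster_id),
                        sort))
  key <- function(p) sort(vapply(p, paste, "", collapse = ","))
  expect_equal(key(mine), key(parts))
})

test_that("more gap never un-clusters loci", {
  set.seed(31)
  n <- 25L
  loci <- data.frame(mirna_id = paste0("m", 1:n), chrom = "chr1",
                     start = sample.int(40000L, n),
                     stringsAsFactors = FALSE)
  loci$end <- loci$start + 22L
  sizes <- vapply(c(100L, 1000L, 5000L, 20000L), function(g)
    nrow(cluster_loci(loci, gap = g)$members), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("cluster direction concordance follows the DE calls", {
  loci <- loci_df(c("a", "b", "c", "d"), rep(c("chr1", "chr2"), each = 2),
                  c(100L, 500L, 100L, 500L), c(122L, 522L, 122L, 522L))
  cl <- cluster_loci(loci, gap = 10000)
  de <- data.frame(mirna_id = c("a", "b", "c", "d"),
                   direction = c("down", "down", "up", "down"),
                   stringsAsFactors = FALSE)
  conc <- cluster_de_concordance(cl, de)
  conc <- conc[order(conc$chrom), ]
  expect_equal(conc$concordant, c(TRUE, FALSE))

  # one member missing from the DE table is tolerated if the rest agree
  de_miss <- de[de$mirna_id != "b", ]
  conc2 <- cluster_de_concordance(cl, de_miss)
  expect_true(conc2$concordant[conc2$chrom == "chr1"])
  expect_equal(conc2$n_missing[conc2$chrom == "chr1"], 1L)

  # a present member with direction none breaks concordance
  de_none <- de; de_none$direction[2] <- "none"
  conc3 <- cluster_de_concordance(cl, de_none)
  expect_false(conc3$concordant[conc3$chrom == "chr1"])
})
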