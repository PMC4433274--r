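test_that("seed-complement sites are found at exact offsets", {
  # seed AGCUUAU -> reverse complement AUAAGCU
  mir <- data.frame(mirna_id = "m1",
                    mature_sequence = "UAGCUUAUCAGACUGAUGUUGA",
                    stringsAsFactors = FALSE)
  utr <- c(geneA = paste0("GGGGG", "AUAAGCU", "CCCCCCCC"))
  sites <- predict_targets(mir, utr)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$utr_offset, 5L)
  expect_equal(sites$site_sequence, "AUAAGCU")
  expect_equal(substr(utr[[1]], 6, 12), sites$site_sequence)

  # a single flipped base removes the site
  utr_flip <- c(geneA = paste0("GGGGG", "AUAACCU", "CCCCCCCC"))
  expect_equal(nrow(predict_targets(mir, utr_flip)), 0L)

  expect_warning(out <- predict_targets(mir, character(0)), "empty UTR")
  expect_equal(nrow(out), 0L)
})

test_that("site lists equal the naive scan oracle, overlaps included", {
  set.seed(3030)
  for (i in 1:50) {
    mir <- data.frame(mirna_id = "m", mature_sequence = random_rna(22),
                      stringsAsFactors = FALSE)
    utr <- c(g = random_rna(120))
    got <- predict_targets(mir, utr)$utr_offset
    want <- oracle_site_offsets(revcomp_rna(extract_seed(
      mir$mature_sequence)), utr[[1]])
    expect_equal(got, want, info = paste("case", i))
  }
  # overlapping occurrences are all reported
  mir_a <- data.frame(mirna_id = "m", mature_sequence =
                        "CUUUUUUUCCCCCCCCCCCCCC", stringsAsFactors = FALSE)
  # seed UUUUUUU -> rc AAAAAAA; poly-A UTR has n-6 overlapping sites
  utr_a <- c(g = paste(rep("A", 10), collapse = ""))
  expect_equal(predict_targets(mir_a, utr_a)$utr_offset, 0:3)
})

test_that("pathway relatedness counts distinct genes only", {
  cfg <- pipeline_config()
  sites <- data.frame(
    mirna_id = c(rep("m1", 5), "m2", "m2", "m3"),
    gene_id = c(rep("SMAD4", 5), "SMAD4", "TGFB3", "GENE01"),
    utr_offset = 0L, site_sequence = "AAAAAAA", stringsAsFactors = FALSE)
  pw <- c("SMAD4", "TGFB3", "TGFBR1")
  out <- assess_pathway(sites, pw, cfg)
  out <- out[match(c("m1", "m2", "m3"), out$mirna_id), ]
  expect_equal(out$n_targeted, c(1L, 2L, 0L))
  expect_equal(out$related, c(FALSE, TRUE, FALSE))
  # empty pathway set: nobody related
  none <- assess_pathway(sites, character(0), cfg)
  expect_true(all(!none$related))
  # adding sites never revokes relatedness
  more <- rbind(sites, data.frame(mirna_id = "m1", gene_id = "TGFBR1",
                                  utr_offset = 3L, site_sequence = "AAAAAAA"))
  out2 <- assess_pathway(more, pw, cfg)
  expect_true(out2$related[out2$mirna_id == "m1"])
  expect_true(out2$related[out2$mirna_id == "m2"])
})

test_that("equal seeds imply identical predicted target-gene sets", {
  set.seed(909)
  seed7 <- random_rna(7)
  mirs <- data.frame(
    mirna_id = c("a", "b"),
    mature_sequence = c(paste0("U", seed7, random_rna(14)),
                        paste0("C", seed7, random_rna(12))),
    stringsAsFactors = FALSE)
  utrs <- stats::setNames(vapply(1:8, function(i) random_rna(150), ""),
                          paste0("g", 1:8))
  utrs[["g3"]] <- paste0(substr(utrs[["g3"]], 1, 50), revcomp_rna(seed7),
                         substr(utrs[["g3"]], 58, 150))
  sites <- predict_targets(mirs, utrs)
  genes_of <- function(id) sort(unique(sites$gene_id[sites$mirna_id == id]))
  expect_equal(genes_of("a"), genes_of("b"))
  expect_true("g3" %in% genes_of("a"))
})

test_that("pathway summary partitions related miRNAs by origin/direction", {
  de <- data.frame(
    mirna_id = c("k1", "k2", "k3", "n1", "n2", "x1"),
    direction = c("up", "down", "down", "up", "down", "none"),
    differential = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    origin = c("known", "known", "known", "novel", "novel", "novel"),
    stringsAsFactors = FALSE)
  assess <- data.frame(
    mirna_id = c("k1", "k2", "n1", "n2", "zz"),
    pathway_name = "pathway", targeted_primary_genes = "",
    n_targeted = 2L, related = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  expect_warning(s <- pathway_summary(assess, de), "missing from DE")
  expect_equal(s$n_related, 3L)
  expect_equal(s$n_de, 5L)
  expect_equal(s$n_de_novel, 2L)
  expect_equal(s$n_related_novel, 1L)
  expect_equal(s$pct_related_novel, 50)
  expect_equal(unname(s$cells["known", "up"]), 1L)
  expect_equal(unname(s$cells["known", "down"]), 1L)
  expect_equal(sum(s$cells), s$n_related)
  expect_equal(s$pct_up_regulated, 40)  # 2 of 5 differential are up
})
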