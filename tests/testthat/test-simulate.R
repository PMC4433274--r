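test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(tiny_spec(rng_seed = 3), d1)
  simulate_dataset(tiny_spec(rng_seed = 3), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(tiny_spec(rng_seed = 4), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("planted hairpins pass the discovery hairpin check", {
  spec <- tiny_spec(rng_seed = 11, n_novel_hairpins = 5L)
  ga <- simulate_genome_and_annotation(spec)
  hp <- ga$truth$hairpins
  expect_equal(nrow(hp), 5L)
  cfg <- pipeline_config()
  for (i in seq_len(nrow(hp))) {
    win <- mirflow:::excise_window(
      ga$genome, hp$chrom[i],
      hp$mature_start[i] - cfg$precursor_upstream,
      hp$mature_end[i] + cfg$precursor_downstream, hp$strand[i])
    h <- assess_hairpin(win$sequence, hp$mature_sequence[i], cfg)
    expect_true(h$is_hairpin, info = hp$hp_id[i])
  }
})

test_that("decoy loci rarely pass the hairpin check (over seeds)", {
  cfg <- pipeline_config()
  ok_seeds <- 0L
  for (s in 1:20) {
    spec <- tiny_spec(rng_seed = 1000L + s, n_decoy_loci = 5L,
                      n_novel_hairpins = 1L, n_known_mirnas = 6L)
    ga <- simulate_genome_and_annotation(spec)
    dec <- ga$truth$decoys
    fails <- 0L
    for (i in seq_len(nrow(dec))) {
      mat <- normalize_rna(substr(ga$genome[[dec$chrom[i]]],
                                  dec$start[i] + 1L, dec$start[i] + 22L))
      win <- mirflow:::excise_window(
        ga$genome, dec$chrom[i], dec$start[i] - cfg$precursor_upstream,
        dec$start[i] + 22L + cfg$precursor_downstream, "+")
      hit <- mirflow:::count_occurrences(mat, win$sequence) == 1L &&
        assess_hairpin(win$sequence, mat, cfg)$is_hairpin
      if (!hit) fails <- fails + 1L
    }
    if (fails >= 4L) ok_seeds <- ok_seeds + 1L
  }
  expect_gte(ok_seeds, 18L)
})

test_that("emitted known-miRNA read counts match the count table", {
  spec <- tiny_spec(rng_seed = 21)
  ga <- simulate_genome_and_annotation(spec)
  cnt <- simulate_counts(spec, ga)
  known_seq <- normalize_rna(ga$truth$known$sequence)
  emitted <- vapply(cnt$reads_by_sample, function(r)
    sum(r$count[r$sequence %in% known_seq]), numeric(1))
  expect_equal(unname(emitted), unname(colSums(cnt$table$counts)))
  # per-sample totals are the genome-matched denominators
  expect_equal(cnt$table$denominators,
               unname(cnt$truth$per_sample_totals))
})

test_that("dispersion zero makes counts deterministic at the means", {
  mu <- matrix(c(3, 7.4, 120, 0.2), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(mirflow:::draw_counts(mu, 0), round(mu))
  set.seed(1)
  nb <- mirflow:::draw_counts(mu, 0.2)
  expect_true(all(nb >= 0) && all(nb == floor(nb)))

  # planted ratio 1 with no noise: the DE stage flags nothing
  spec <- tiny_spec(rng_seed = 8, dispersion = 0, prop_up = 0,
                    prop_down = 0)
  ga <- simulate_genome_and_annotation(spec)
  cnt <- simulate_counts(spec, ga)
  de <- call_de(cnt$table)
  expect_equal(sum(de$differential), 0L)
})

test_that("with vanishing noise the DE calls recover truth exactly", {
  spec <- tiny_spec(rng_seed = 13, dispersion = 0, n_known_mirnas = 20L)
  ga <- simulate_genome_and_annotation(spec)
  cnt <- simulate_counts(spec, ga)
  de <- call_de(cnt$table)
  called <- sort(de$mirna_id[de$differential])
  planted <- sort(intersect(ga$truth$true_de_set, de$mirna_id))
  expect_equal(called, planted)
  # directions match the planted ratios
  for (id in planted) {
    r <- ga$truth$ratios[[id]]
    expect_equal(de$direction[de$mirna_id == id],
                 if (r > 1) "up" else "down", info = id)
  }
})

test_that("planted UTR sites are exactly recoverable", {
  spec <- tiny_spec(rng_seed = 17)
  ga <- simulate_genome_and_annotation(spec)
  utr <- simulate_utrs_and_pathway(spec, ga)
  truth_sites <- utr$truth$target_sites
  expect_gt(nrow(truth_sites), 0)
  hp <- ga$truth$hairpins
  mirnas <- rbind(
    data.frame(mirna_id = ga$annotation$name,
               mature_sequence = ga$annotation$mature_sequence,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = hp$hp_id, mature_sequence = hp$mature_sequence,
               stringsAsFactors = FALSE))
  sites <- predict_targets(mirnas, utr$utrs)
  # every planted site is found at its recorded offset
  for (i in seq_len(nrow(truth_sites))) {
    hit <- sites[sites$mirna_id == truth_sites$mirna_id[i] &
                 sites$gene_id == truth_sites$gene_id[i] &
                 sites$utr_offset == truth_sites$utr_offset[i], ]
    expect_equal(nrow(hit), 1L,
                 info = paste(truth_sites$mirna_id[i],
                              truth_sites$gene_id[i]))
  }
  # pathway classification matches the planted design
  assess <- assess_pathway(sites, utr$pathway_genes,
                           mirna_ids = mirnas$mirna_id)
  related <- sort(assess$mirna_id[assess$related])
  # seed sharing can only add relatedness beyond the planted set
  expect_true(all(sort(utr$truth$pathway_related) %in% related))
  planted_lists <- utr$truth$planted_sites
  one_gene <- names(planted_lists)[vapply(planted_lists, function(g)
    length(intersect(g, utr$pathway_genes)), integer(1)) == 1L]
  seeds <- extract_seed(stats::setNames(mirnas$mature_sequence,
                                        mirnas$mirna_id))
  rel_seeds <- seeds[utr$truth$pathway_related]
  solo <- one_gene[!seeds[one_gene] %in% rel_seeds]
  expect_true(all(!assess$related[assess$mirna_id %in% solo]))
})
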