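test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_genes = 40, n_scaffolds = 1,
                           scaffold_length_bp = 100000)
  s1 <- simulate_genome(cfg, seed = 5)
  s2 <- simulate_genome(cfg, seed = 5)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  g1 <- tempfile(fileext = ".gff3"); g2 <- tempfile(fileext = ".gff3")
  write_fasta(s1$genome, f1); write_fasta(s2$genome, f2)
  write_gff3(s1$genes, g1, nchar(s1$genome))
  write_gff3(s2$genes, g2, nchar(s2$genome))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))

  s3 <- simulate_genome(cfg, seed = 6)
  expect_false(identical(s1$genome, s3$genome))
})

test_that("background composition matches the configured AT fraction", {
  cfg <- simulation_config(n_genes = 2, n_scaffolds = 1,
                           scaffold_length_bp = 1000000)
  sim <- simulate_genome(cfg, seed = 13)
  comp <- table(strsplit(sim$genome[[1]], "")[[1]])
  at <- sum(comp[c("A", "T")]) / sum(comp)
  expect_lte(abs(at - 0.642), 0.01)
})

test_that("a pure head-to-head mixture plants only head-to-head pairs", {
  cfg <- simulation_config(n_genes = 60, n_scaffolds = 1,
                           scaffold_length_bp = 200000,
                           orientation_mix = c(1, 0, 0))
  sim <- simulate_genome(cfg, seed = 17)
  pairs <- adjacent_pairs(sim$genes)
  key <- paste(pairs$left_gene_id, pairs$right_gene_id)
  tkey <- paste(sim$truth$pairs$left_gene_id, sim$truth$pairs$right_gene_id)
  expect_true(all(pairs$category[match(tkey, key)] == "head_to_head"))
  expect_true(all(sim$truth$pairs$tss_distance_bp <= 1000))
  # configured TSS distances are realised exactly
  expect_equal(pairs$tss_distance_bp[match(tkey, key)],
               sim$truth$pairs$tss_distance_bp)
})

test_that("infeasible packing raises an error", {
  cfg <- simulation_config(n_genes = 200, n_scaffolds = 1,
                           scaffold_length_bp = 30000)
  expect_error(simulate_genome(cfg, seed = 1), "infeasible packing")
})

test_that("motifs planted everywhere are recovered at the exact offsets", {
  sim <- small_sim()
  pr <- filter_promoters(extract_core_promoters(sim$genes, sim$genome),
                         sim$genome)
  pl <- plant_motifs(sim$genome, pr,
                     list(list(consensus = "AWTAAA", offset_mean = -30,
                               offset_sd = 0, fraction = 1)), seed = 19)
  expect_equal(nrow(pl$truth), sum(pr$status == "retained"))
  # every planted instance sits at its recorded genomic coordinate
  for (i in sample(nrow(pl$truth), 25)) {
    tr <- pl$truth[i, ]
    site <- substr(pl$genome[[tr$scaffold_id]], tr$genomic_start + 1,
                   tr$genomic_start + nchar(tr$instance))
    expect_identical(site,
                     if (tr$strand == "+") tr$instance
                     else revcomp(tr$instance))
  }
  # scan recovers a hit at every truth offset
  ret <- pr[pr$status == "retained", ]
  hits_by_gene <- lapply(seq_len(nrow(ret)), function(i) {
    seqs <- substr(pl$genome[[ret$scaffold_id[i]]],
                   min(ret$start[i], ret$end[i]) + 1,
                   max(ret$start[i], ret$end[i]))
    if (ret$strand[i] == "-") seqs <- revcomp(seqs)
    scan_iupac(seqs, "AWTAAA")$start - 150L
  })
  names(hits_by_gene) <- ret$gene_id
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    expect_true(tr$offset %in% hits_by_gene[[tr$gene_id]])
  }
})

test_that("fractional planting recovers the planted promoter share", {
  sim <- small_sim()
  pr <- filter_promoters(extract_core_promoters(sim$genes, sim$genome),
                         sim$genome)
  pl <- plant_motifs(sim$genome, pr,
                     list(list(consensus = "GGGGCGGGG", offset_mean = -30,
                               offset_sd = 3, fraction = 0.5)), seed = 23)
  ret <- pr[pr$status == "retained", ]
  anchors <- data.frame(scaffold_id = ret$scaffold_id,
                        position = ret$tss_position, strand = ret$strand)
  prof <- positional_profile(anchors, pl$genome, gcbox_motif())
  recovered <- length(unique(prof$hits$anchor)) / prof$n_regions
  planted <- length(unique(pl$truth$gene_id)) / nrow(ret)
  expect_lte(abs(recovered - planted), 0.01)   # truth-scan concordance
  expect_lte(abs(recovered - 0.5), 0.10)       # binomial at n = 200
})

test_that("empty plant lists leave the genome unchanged", {
  sim <- small_sim()
  pr <- filter_promoters(extract_core_promoters(sim$genes, sim$genome),
                         sim$genome)
  pl <- plant_motifs(sim$genome, pr, list(), seed = 29)
  expect_identical(pl$genome, sim$genome)
  expect_equal(nrow(pl$truth), 0)
})

test_that("zero planting rates give flat zero cumulative profiles", {
  sim <- small_sim()
  tss <- derive_tss(sim$genes)[1:50, ]
  pd <- plant_directionality_signals(sim$genome, tss,
                                     pas_rates = c(0, 0),
                                     ss5_rates = c(0, 0), seed = 31)
  expect_identical(pd$genome, sim$genome)
  expect_equal(nrow(pd$truth), 0)
})

test_that("directional planting is reproducible and strand-correct", {
  sim <- small_sim()
  tss <- derive_tss(sim$genes)[1:40, ]
  pd1 <- plant_directionality_signals(sim$genome, tss,
                                      pas_rates = c(2, 2),
                                      ss5_rates = c(0, 0), seed = 37)
  pd2 <- plant_directionality_signals(sim$genome, tss,
                                      pas_rates = c(2, 2),
                                      ss5_rates = c(0, 0), seed = 37)
  expect_identical(pd1$genome, pd2$genome)
  expect_identical(pd1$truth, pd2$truth)
  # every planted site is scannable at its recorded distance
  for (i in seq_len(min(30, nrow(pd1$truth)))) {
    tr <- pd1$truth[i, ]
    right <- (tr$strand == "+") == (tr$direction == "sense_downstream")
    raw <- substr(pd1$genome[[tr$scaffold_id]], tr$genomic_start + 1,
                  tr$genomic_start + nchar(tr$instance))
    expect_identical(if (right) raw else revcomp(raw), tr$instance)
  }
})
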