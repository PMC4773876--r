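test_that("FASTA reading normalises case and ambiguity codes", {
  p <- write_temp_fasta(list(s1 = "ACGT"))
  g <- read_genome(p)
  expect_identical(g, c(s1 = "ACGT"))

  p <- write_temp_fasta(list(s1 = "acgt"))
  expect_identical(unname(read_genome(p)["s1"]), "ACGT")

  p <- write_temp_fasta(list(s1 = "ACRT"))
  expect_warning(g <- read_genome(p), "mapped to N")
  expect_identical(unname(g["s1"]), "ACNT")

  p <- write_temp_fasta(list(s1 = "ACGT", s2 = "AAAA"))
  expect_length(read_genome(p), 2)

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s1", "TTTT"), dup)
  expect_error(read_genome(dup), "duplicate")
})

test_that("GFF3 gene models convert coordinates and filter biotypes", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gene:gA",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=tA;Parent=gene:gA;biotype=protein_coding",
    "chr1\tsrc\texon\t1\t40\t.\t+\t.\tParent=tA",
    "chr1\tsrc\texon\t61\t100\t.\t+\t.\tParent=tA",
    "chr1\tsrc\tCDS\t21\t90\t.\t+\t0\tParent=tA",
    "chr1\tsrc\tgene\t201\t300\t.\t-\t.\tID=gene:gB",
    "chr1\tsrc\tmRNA\t201\t300\t.\t-\t.\tID=tB;Parent=gene:gB;biotype=lncRNA",
    "chr1\tsrc\texon\t201\t300\t.\t-\t.\tParent=tB"
  ), p)
  g <- read_gene_models(p, "gff3")
  expect_equal(nrow(g), 1)  # lncRNA excluded
  expect_equal(g$tx_start, 0L)
  expect_equal(g$tx_end, 100L)
  expect_equal(g$cds_start, 20L)
  expect_equal(g$cds_end, 90L)
  expect_true(g$has_annotated_5utr)
  expect_equal(g$exons[[1]][, "start"], c(0L, 60L), ignore_attr = TRUE)

  # feature beyond the declared scaffold length is an error
  bad <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 50",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=tX"
  ), bad)
  expect_error(read_gene_models(bad, "gff3"), "outside declared scaffold")
})

test_that("BED12 gene models read native half-open coordinates", {
  p <- tempfile(fileext = ".bed")
  writeLines(paste(
    "chr1", 0, 100, "tx1", 0, "-", 10, 90, "0,0,0", 2, "30,40,", "0,60,",
    sep = "\t"), p)
  g <- read_gene_models(p, "bed12")
  expect_equal(g$tx_start, 0L)
  expect_equal(g$tx_end, 100L)
  expect_equal(g$strand, "-")
  expect_equal(g$cds_start, 10L)
  expect_equal(g$exons[[1]], cbind(start = c(0L, 60L), end = c(30L, 100L)),
               ignore_attr = TRUE)
})

test_that("BED12 round-trip preserves intervals and strands exactly", {
  set.seed(4)
  genes <- do.call(rbind, lapply(1:20, function(i) {
    s <- sample(1:5000, 1)
    ex1 <- c(s, s + sample(50:200, 1))
    ex2 <- c(ex1[2] + sample(30:100, 1), 0)
    ex2[2] <- ex2[1] + sample(50:200, 1)
    gm(sprintf("t%02d", i), sample(c("c1", "c2"), 1),
       sample(c("+", "-"), 1), s, ex2[2],
       cds_start = s + 10, cds_end = ex2[2] - 10,
       exons = cbind(start = c(ex1[1], ex2[1]), end = c(ex1[2], ex2[2])))
  }))
  p <- tempfile(fileext = ".bed")
  write_bed12(genes, p)
  back <- read_gene_models(p, "bed12")
  back <- back[match(genes$gene_id, back$gene_id), ]
  expect_equal(back$tx_start, genes$tx_start)
  expect_equal(back$tx_end, genes$tx_end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$cds_start, genes$cds_start)
  expect_equal(back$cds_end, genes$cds_end)
  for (i in seq_len(nrow(genes))) {
    expect_equal(back$exons[[i]], genes$exons[[i]], ignore_attr = TRUE)
  }
})

test_that("GFF3 writer output reads back identically", {
  sim <- small_sim()
  genes <- sim$genes[1:30, ]
  p <- tempfile(fileext = ".gff3")
  write_gff3(genes, p, seqlens = nchar(sim$genome))
  back <- read_gene_models(p, "gff3")
  back <- back[match(genes$gene_id, back$gene_id), ]
  expect_equal(back$tx_start, genes$tx_start)
  expect_equal(back$tx_end, genes$tx_end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$has_annotated_5utr, genes$has_annotated_5utr)
  for (i in seq_len(nrow(genes))) {
    expect_equal(back$exons[[i]], genes$exons[[i]], ignore_attr = TRUE)
  }
})

test_that("TSS derivation collapses strand-aware duplicates", {
  g <- gms(
    gm("a1", "c1", "+", 100, 500, 150, 480),
    gm("a2", "c1", "+", 100, 900, 200, 880),  # same TSS as a1
    gm("a3", "c1", "-", 50, 101, 60, 95),     # TSS 100 on the other strand
    gm("a4", "c1", "-", 200, 500, 220, 480)
  )
  tss <- derive_tss(g)
  expect_equal(nrow(tss), 3)
  plus <- tss[tss$strand == "+", ]
  expect_equal(plus$position, 100L)
  expect_equal(plus$n_collapsed, 2L)
  minus <- tss[tss$strand == "-", ]
  expect_setequal(minus$position, c(100L, 499L))
  expect_equal(sum(tss$n_collapsed), nrow(g))
})

test_that("TSS count is bounded by gene count with conserved collapse mass", {
  sim <- small_sim()
  tss <- derive_tss(sim$genes)
  expect_lte(nrow(tss), nrow(sim$genes))
  expect_equal(sum(tss$n_collapsed), nrow(sim$genes))
  key <- paste(tss$scaffold_id, tss$position, tss$strand)
  expect_false(anyDuplicated(key) > 0)
})
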