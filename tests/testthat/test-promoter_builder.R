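test_that("core-promoter windows follow the strand conventions", {
  set.seed(21)
  sc <- c(s = rand_dna(2000))
  gp <- gm("p", "s", "+", 1000, 1500, 1100, 1450)
  gn <- gm("n", "s", "-", 500, 1001, 550, 950)
  pr <- extract_core_promoters(gms(gp, gn), sc)

  plus <- pr[pr$gene_id == "p", ]
  expect_equal(c(plus$start, plus$end), c(850L, 1050L))
  expect_equal(nchar(plus$sequence), 200L)
  # TSS maps to sense index `upstream` (0-based): sequence char 151
  expect_equal(substr(plus$sequence, 151, 151),
               substr(sc[["s"]], 1001, 1001))

  minus <- pr[pr$gene_id == "n", ]
  expect_equal(c(minus$start, minus$end), c(951L, 1151L))
  expect_equal(substr(minus$sequence, 151, 151),
               revcomp(substr(sc[["s"]], 1001, 1001)))

  near_edge <- gm("e", "s", "+", 100, 400, 150, 380)
  pre <- extract_core_promoters(gms(near_edge), sc)
  expect_equal(pre$status, "rejected")
  expect_equal(pre$rejection_reason, "off_scaffold")

  no_utr <- gm("u", "s", "+", 1000, 1500, 1000, 1450)
  pru <- extract_core_promoters(gms(no_utr), sc)
  expect_equal(pru$rejection_reason, "no_5utr")
})

test_that("gap detection reports maximal N runs as half-open intervals", {
  expect_equal(detect_gaps("ACGNNNACG")$start, 3L)
  expect_equal(detect_gaps("ACGNNNACG")$end, 6L)
  expect_equal(nrow(detect_gaps("ACGTACGT")), 0)
  g <- detect_gaps("NNNN")
  expect_equal(c(g$start, g$end), c(0L, 4L))
  expect_equal(nrow(detect_gaps("ACGNNNACG", min_run = 4)), 0)
})

test_that("CpG island detection finds homogeneous and embedded islands", {
  cg12 <- paste(rep("CG", 6000), collapse = "")
  isl <- detect_cpg_islands(cg12)
  expect_equal(nrow(isl), 1)
  expect_gte(isl$end - isl$start, 10000)
  expect_gte(isl$gc_fraction, 0.99)
  expect_gte(isl$obs_exp_cpg, 0.6)

  allA <- paste(rep("A", 12000), collapse = "")
  expect_equal(nrow(detect_cpg_islands(allA)), 0)

  set.seed(31)
  flank1 <- rand_dna(20000, at = 0.8)
  flank2 <- rand_dna(18000, at = 0.8)
  emb <- paste0(flank1, cg12, flank2)
  isl2 <- detect_cpg_islands(emb)
  expect_equal(nrow(isl2), 1)
  expect_lte(abs(isl2$start - 20000), 200)
  expect_lte(abs(isl2$end - 32000), 200)
})

test_that("promoter filters apply their precedence rules", {
  set.seed(41)
  long_sc <- rand_dna(20000)
  genes <- gms(
    gm("iso", "big", "+", 5000, 6000, 5100, 5900),
    gm("ovA", "big", "+", 9000, 9800, 9100, 9700),
    gm("ovB", "big", "+", 9100, 9900, 9200, 9800),  # promoter overlaps ovA's
    gm("shrt", "tiny", "+", 5000, 6000, 5100, 5900),
    gm("gap", "gappy", "+", 5000, 6000, 5100, 5900)
  )
  gappy <- long_sc
  substr(gappy, 4900, 4920) <- paste(rep("N", 21), collapse = "")
  sc <- c(big = long_sc, tiny = substr(long_sc, 1, 9000), gappy = gappy)
  pr <- filter_promoters(extract_core_promoters(genes, sc), sc)

  expect_equal(pr$status[pr$gene_id == "iso"], "retained")
  expect_equal(pr$rejection_reason[pr$gene_id == "ovA"], "overlaps_promoter")
  expect_equal(pr$rejection_reason[pr$gene_id == "ovB"], "overlaps_promoter")
  expect_equal(pr$rejection_reason[pr$gene_id == "shrt"], "short_scaffold")
  expect_equal(pr$rejection_reason[pr$gene_id == "gap"], "overlaps_gap")

  # partition: retained xor exactly one rejection reason
  expect_true(all((pr$status == "retained") == is.na(pr$rejection_reason)))

  # retained promoters are mutually non-overlapping
  ret <- pr[pr$status == "retained", ]
  if (nrow(ret) > 1) {
    for (i in 1:(nrow(ret) - 1)) {
      for (j in (i + 1):nrow(ret)) {
        same <- ret$scaffold_id[i] == ret$scaffold_id[j]
        expect_false(same && ret$start[i] < ret$end[j] &&
                       ret$end[i] > ret$start[j])
      }
    }
  }
})

test_that("a CpG-contaminated scaffold rejects its promoters", {
  set.seed(43)
  sc <- c(cgy = paste0(rand_dna(15000, at = 0.8),
                       paste(rep("CG", 6000), collapse = ""),
                       rand_dna(15000, at = 0.8)))
  g <- gm("c1", "cgy", "+", 5000, 6000, 5100, 5900)
  pr <- filter_promoters(extract_core_promoters(gms(g), sc), sc)
  expect_equal(pr$rejection_reason, "cpg_contamination")
})

test_that("promoter extraction is strand-mirror symmetric", {
  set.seed(51)
  L <- 30000L
  sc <- c(s = rand_dna(L))
  genes <- do.call(rbind, lapply(1:15, function(i) {
    s <- sample(2000:(L - 3000), 1)
    e <- s + sample(500:1500, 1)
    st <- sample(c("+", "-"), 1)
    gm(sprintf("g%02d", i), "s", st, s, e,
       cds_start = s + 100, cds_end = e - 100)
  }))
  pr <- extract_core_promoters(genes, sc)

  mirrored <- genes
  mirrored$tx_start <- L - genes$tx_end
  mirrored$tx_end <- L - genes$tx_start
  mirrored$cds_start <- L - genes$cds_end
  mirrored$cds_end <- L - genes$cds_start
  mirrored$strand <- ifelse(genes$strand == "+", "-", "+")
  mirrored$has_annotated_5utr <- genes$has_annotated_5utr
  prm <- extract_core_promoters(mirrored, c(s = revcomp(sc[["s"]])))

  for (i in seq_len(nrow(genes))) {
    expect_identical(prm$sequence[i], pr$sequence[i])
  }
})
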