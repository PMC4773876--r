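test_that("log-odds PWM construction follows the stated formula", {
  pfm <- matrix(c(10, 0, 0, 0), 4, 1)
  pwm <- build_pwm(pfm, background = rep(0.25, 4), pseudocount = 1)
  expect_equal(unname(pwm["A", 1]), log2((10.25 / 11) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm["A", 1]), 1.898, tolerance = 5e-4)

  eq <- build_pwm(matrix(5, 4, 3), background = rep(0.25, 4),
                  pseudocount = 1)
  expect_true(all(abs(eq) < 1e-12))

  pfm2 <- matrix(c(4, 3, 2, 1), 4, 1)
  bg2 <- c(0.4, 0.3, 0.2, 0.1)
  expect_true(all(abs(build_pwm(pfm2, bg2, pseudocount = 0)) < 1e-12))

  expect_error(build_pwm(matrix(0, 4, 2), pseudocount = 0), "all-zero")
})

test_that("IUPAC matching honours degenerate classes and rejects N", {
  expect_equal(scan_iupac("AATAAA", "AWTAAA")$start, 0L)
  expect_equal(scan_iupac("ATTAAA", "AWTAAA")$start, 0L)
  expect_equal(nrow(scan_iupac("AAAAAA", "AWTAAA")), 0)
  expect_equal(nrow(scan_iupac("AANAAA", "AWTAAA")), 0)
  expect_equal(nrow(scan_iupac("AANAAA", "AANAAA")), 0)  # N never matches
  expect_error(scan_iupac("ACGT", "AXGT"), "invalid IUPAC")
  # U in a consensus is DNA T
  expect_equal(scan_iupac("AATAAA", "AWUAAA")$start, 0L)
})

test_that("PWM scanning reports consensus windows and respects width", {
  m <- motif_model("tata", pfm = matrix(c(
    0, 0, 0, 20,  20, 0, 0, 0,  0, 0, 0, 20,  20, 0, 0, 0), 4, 4))
  set.seed(71)
  s <- paste0(rand_dna(40, at = 0), "TATA", rand_dna(40, at = 0))
  h <- scan_pwm(s, m)
  expect_true(40 %in% h$start)
  expect_equal(h$site[h$start == 40], "TATA")
  expect_equal(nrow(scan_pwm("TAT", m)), 0)
})

test_that("scanners agree exactly with per-window oracles", {
  set.seed(73)
  motifs <- list(
    motif_model("pas", consensus = "AWTAAA"),
    motif_model("gc", consensus = "GGGGCGGGG"),
    motif_model("donor", pfm = synthetic_donor_pfm(), score_threshold = 0.7),
    motif_model("tata_pwm", pfm = matrix(c(
      1, 1, 1, 17,  16, 2, 1, 1,  0, 0, 0, 20,  18, 0, 1, 1,
      10, 0, 0, 10), 4, 5), score_threshold = 0.85),
    motif_model("skewed", pfm = matrix(c(
      8, 4, 2, 6,  1, 9, 9, 1,  5, 5, 5, 5,  0, 0, 20, 0), 4, 4),
      background = c(0.321, 0.179, 0.179, 0.321), score_threshold = 0.75)
  )
  for (rep in 1:20) {
    s <- rand_dna(sample(100:400, 1), at = 0.642)
    if (rep %% 5 == 0) substr(s, 50, 52) <- "NNN"
    for (m in motifs) {
      if (m$kind == "iupac") {
        got <- scan_iupac(s, m)
        expect_identical(got$start, oracle_scan_iupac(s, m$consensus))
      } else {
        got <- scan_pwm(s, m)
        want <- oracle_scan_pwm(s, m)
        expect_identical(got$start, as.integer(want$start))
        expect_equal(got$score, want$score, tolerance = 1e-10)
      }
    }
  }
})

test_that("both-strand scanning is reverse-complement symmetric", {
  set.seed(79)
  m <- motif_model("donor", pfm = synthetic_donor_pfm(),
                   score_threshold = 0.7)
  pas <- motif_model("pas", consensus = "AWTAAA")
  for (rep in 1:10) {
    s <- rand_dna(300, at = 0.642)
    L <- nchar(s)
    for (mm in list(m, pas)) {
      h <- if (mm$kind == "pwm") scan_pwm(s, mm, "both")
           else scan_iupac(s, mm, "both")
      hr <- if (mm$kind == "pwm") scan_pwm(revcomp(s), mm, "both")
            else scan_iupac(revcomp(s), mm, "both")
      # reflect: start' = L - w - start, strand swapped
      reflected <- data.frame(
        start = as.integer(L - mm$width - hr$start),
        strand = as.character(ifelse(hr$strand == "sense",
                                     "antisense", "sense")),
        stringsAsFactors = FALSE
      )
      o1 <- h[order(h$start, h$strand), c("start", "strand")]
      o2 <- reflected[order(reflected$start, reflected$strand), ,
                      drop = FALSE]
      expect_equal(nrow(o1), nrow(o2))
      if (nrow(o1) > 0) {
        expect_equal(o1$start, o2$start)
        expect_equal(o1$strand, o2$strand)
      }
    }
  }
})

test_that("raising the score threshold never adds hits", {
  set.seed(83)
  s <- rand_dna(2000, at = 0.642)
  thr <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  hits <- lapply(thr, function(t)
    scan_pwm(s, motif_model("d", pfm = synthetic_donor_pfm(),
                            score_threshold = t))$start)
  for (k in 2:length(thr)) {
    expect_true(all(hits[[k]] %in% hits[[k - 1]]))
  }
})

test_that("positional profiles bin hits by anchor-relative offset", {
  set.seed(89)
  sc <- c(s = rand_dna(2000, at = 1))  # all A/T, no GC-box background
  g <- c(s = sc[["s"]])
  substr(g["s"], 1000 - 35 + 1, 1000 - 35 + 9) <- "GGGGCGGGG"
  anchors <- data.frame(scaffold_id = "s", position = 1000L, strand = "+")
  prof <- positional_profile(anchors, g, gcbox_motif())
  expect_equal(length(prof$frequency), 50)
  expect_equal(prof$n_regions, 1)
  # offset -35 falls in the bin covering [-40, -30)
  b <- which(prof$bin_start == -40)
  expect_equal(prof$frequency[b], 1)
  expect_equal(sum(prof$frequency[-b]), 0)

  # no hits -> all-zero profile
  prof0 <- positional_profile(anchors, sc, gcbox_motif())
  expect_true(all(prof0$frequency == 0))
})

test_that("profile mass equals total binned hits over regions", {
  sim <- small_sim()
  pr <- filter_promoters(extract_core_promoters(sim$genes, sim$genome),
                         sim$genome)
  ret <- pr[pr$status == "retained", ][1:100, ]
  anchors <- data.frame(scaffold_id = ret$scaffold_id,
                        position = ret$tss_position, strand = ret$strand)
  prof <- positional_profile(anchors, sim$genome, pas_motif())
  expect_equal(sum(prof$frequency) * prof$n_regions, nrow(prof$hits))
  expect_true(all(prof$frequency >= 0))
})

test_that("composition profiles report per-offset base and dinucleotides", {
  g <- c(s = paste(rep("ACGT", 300), collapse = ""))
  anchors <- data.frame(scaffold_id = "s", position = 600L, strand = "+")
  cp <- composition_profile(anchors, g, window = c(-8L, 8L))
  # position 600 is an A (600 %% 4 == 0); offsets -8, -4, 0, 4 are A
  expect_equal(unname(cp$base["A", cp$offsets %% 4 == 0]), rep(1, 4))
  expect_equal(sum(cp$base["A", cp$offsets %% 4 != 0]), 0)

  g2 <- c(s = paste(rep("CG", 500), collapse = ""))
  a2 <- data.frame(scaffold_id = "s", position = 500L, strand = "+")
  cp2 <- composition_profile(a2, g2, window = c(-6L, 6L))
  even <- cp2$offsets[seq(1, length(cp2$offsets) - 1)] %% 2 == 0
  expect_equal(unname(cp2$dinuc["CG", even]), rep(1, sum(even)))
  expect_equal(sum(cp2$dinuc["CG", !even]), 0)
})

test_that("motif file readers recover the synthetic matrices", {
  jf <- system.file("extdata", "synthetic_donor.jaspar",
                    package = "promarch")
  jm <- read_jaspar_pfm(jf)
  expect_equal(unname(jm[[1]]$pfm), unname(synthetic_donor_pfm()))

  mf <- system.file("extdata", "synthetic_motifs.meme",
                    package = "promarch")
  mm <- read_meme_motifs(mf)
  expect_setequal(names(mm), c("TATA_synthetic", "SS5_donor_synthetic"))
  expect_equal(unname(mm$SS5_donor_synthetic$pfm),
               unname(synthetic_donor_pfm()), tolerance = 1e-6)
  expect_equal(mm$TATA_synthetic$background,
               c(0.321, 0.179, 0.179, 0.321))
  # consensus of the probability matrix round-trips through scanning
  expect_equal(scan_pwm("CAGGTAAGT", mm$SS5_donor_synthetic)$start, 0L)
})
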