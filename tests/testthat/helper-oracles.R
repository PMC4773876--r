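# shared fixtures and independent oracles for the scanner / profile tests

rand_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# one-row gene-model builder
gm <- function(id, sc, strand, start, end, cds_start = NA, cds_end = NA,
               exons = NULL) {
  df <- data.frame(gene_id = id, scaffold_id = sc, strand = strand,
                   tx_start = as.integer(start), tx_end = as.integer(end),
                   cds_start = as.integer(cds_start),
                   cds_end = as.integer(cds_end),
                   stringsAsFactors = FALSE)
  df$exons <- list(exons)
  df$has_annotated_5utr <- ifelse(
    is.na(df$cds_start), FALSE,
    ifelse(strand == "+", df$cds_start > df$tx_start,
           df$cds_end < df$tx_end))
  df
}

gms <- function(...) do.call(rbind, list(...))

# IUPAC oracle via regex with overlapping lookahead matches
oracle_scan_iupac <- function(seq, consensus) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
           M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
           N = "[ACGT]")
  cls <- strsplit(toupper(consensus), "")[[1]]
  rx <- paste0("(?=", paste(map[cls], collapse = ""), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# PWM oracle: per-window rescoring straight from the count matrix and the
# stated log-odds formula, one window at a time
oracle_scan_pwm <- function(seq, motif) {
  pfm <- motif$pfm
  bg <- motif$background
  pc <- motif$pseudocount
  w <- ncol(pfm)
  nj <- colSums(pfm)
  prob <- matrix(0, 4, w)
  for (j in 1:w) prob[, j] <- (pfm[, j] + pc * bg) / (nj[j] + pc)
  lo <- log2(prob / bg)
  maxs <- sum(apply(lo, 2, max))
  thr <- motif$score_threshold * maxs
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  res <- list()
  k <- 0
  if (L >= w) {
    for (s in 0:(L - w)) {
      win <- chars[(s + 1):(s + w)]
      idx <- match(win, c("A", "C", "G", "T"))
      sc <- if (anyNA(idx)) -Inf else sum(lo[cbind(idx, 1:w)])
      if (sc >= thr) {
        k <- k + 1
        res[[k]] <- data.frame(start = s, score = sc)
      }
    }
  }
  if (k == 0) data.frame(start = integer(), score = numeric())
  else do.call(rbind, res)
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

# small simulated genome reused across module tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 200, n_scaffolds = 2,
                               scaffold_length_bp = 300000)
      cache <<- simulate_genome(cfg, seed = 7)
    }
    cache
  }
})

# full study-scale genome (default configuration), shared by the
# orientation-recovery property and the acceptance checks
study_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(simulation_config(), seed = 2016)
    }
    cache
  }
})
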