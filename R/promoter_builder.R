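#' Extract core-promoter windows around annotated TSSs
#'
#' For each gene with an annotated 5' UTR, extracts the window `upstream` bp
#' before to `downstream` bp after the TSS (defaults 150/50, a 200 bp core
#' promoter). The genomic interval is `[tss - upstream, tss + downstream)` on
#' the `+` strand and its strand mirror `[tss - downstream + 1, tss + upstream + 1)`
#' on the `-` strand; the reported sequence is always 5'->3' on the gene's
#' sense strand, with the TSS at sequence index `upstream` (0-based).
#'
#' Genes without an annotated 5' UTR are returned with
#' `status = "rejected", rejection_reason = "no_5utr"`; windows running past a
#' scaffold end are rejected as `off_scaffold`. Rejections are data, not
#' errors.
#'
#' @param genes gene-model data.frame
#' @param genome named character vector of scaffold sequences
#' @param upstream,downstream window extent in bp around the TSS
#' @return promoter data.frame with columns `gene_id`, `scaffold_id`,
#'   `strand`, `start`, `end`, `tss_position`, `sequence`, `status`,
#'   `rejection_reason`
#' @export
extract_core_promoters <- function(genes, genome, upstream = 150L,
                                   downstream = 50L) {
  n <- nrow(genes)
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  start <- ifelse(genes$strand == "+", tss - upstream, tss - downstream + 1L)
  end <- ifelse(genes$strand == "+", tss + downstream, tss + upstream + 1L)
  sc_len <- nchar(genome)[genes$scaffold_id]

  status <- rep("retained", n)
  reason <- rep(NA_character_, n)

  no_utr <- !genes$has_annotated_5utr
  status[no_utr] <- "rejected"
  reason[no_utr] <- "no_5utr"

  off <- !no_utr & (start < 0L | end > sc_len | is.na(sc_len))
  status[off] <- "rejected"
  reason[off] <- "off_scaffold"

  seqs <- rep(NA_character_, n)
  ok <- status == "retained"
  if (any(ok)) {
    raw <- substr(genome[genes$scaffold_id[ok]], start[ok] + 1L, end[ok])
    neg <- genes$strand[ok] == "-"
    raw[neg] <- revcomp(raw[neg])
    seqs[ok] <- raw
  }

  data.frame(
    gene_id = genes$gene_id,
    scaffold_id = genes$scaffold_id,
    strand = genes$strand,
    start = as.integer(start),
    end = as.integer(end),
    tss_position = as.integer(tss),
    sequence = seqs,
    status = status,
    rejection_reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Detect assembly gaps (runs of N) in a scaffold
#'
#' @param scaffold_seq one scaffold sequence
#' @param min_run minimum run length to report (default 1: any N)
#' @return data.frame of half-open intervals `start`, `end`
#' @export
detect_gaps <- function(scaffold_seq, min_run = 1L) {
  stopifnot(min_run >= 1)
  m <- gregexpr("N+", scaffold_seq)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  keep <- len >= min_run
  data.frame(start = as.integer(m[keep]) - 1L,
             end = as.integer(m[keep]) - 1L + len[keep])
}

#' Detect CpG islands by sliding-window criteria
#'
#' Classic island criteria: windows of `window` bp (slid by `step`) qualify
#' when GC fraction >= `min_gc` and observed/expected CpG, computed as
#' `(#CG * L) / (#C * #G)`, >= `min_obs_exp`; qualifying windows are merged
#' into maximal intervals and intervals shorter than `min_len` are dropped.
#' The contamination filter uses `min_len = 10000` (very long islands in an
#' AT-rich assembly are a bacterial-contamination signature); pass a smaller
#' `min_len` to see all merged islands.
#'
#' @param scaffold_seq one scaffold sequence
#' @param min_len minimum merged island length returned
#' @param min_gc minimum GC fraction per window
#' @param min_obs_exp minimum observed/expected CpG per window
#' @param window sliding window width (bp)
#' @param step window step (bp)
#' @return data.frame `start`, `end` (half-open), `gc_fraction`,
#'   `obs_exp_cpg` computed over each merged island
#' @export
detect_cpg_islands <- function(scaffold_seq, min_len = 10000L, min_gc = 0.5,
                               min_obs_exp = 0.6, window = 200L, step = 1L) {
  stopifnot(min_len > 0, window > 0, step > 0)
  L <- nchar(scaffold_seq)
  if (L < window) {
    return(data.frame(start = integer(), end = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric()))
  }
  code <- .encode_dna(scaffold_seq)
  isC <- !is.na(code) & code == 2L
  isG <- !is.na(code) & code == 3L
  isCG <- isC[-L] & isG[-1]

  cumC <- c(0, cumsum(isC))
  cumG <- c(0, cumsum(isG))
  cumCG <- c(0, cumsum(isCG))

  starts <- seq.int(0L, L - window, by = step)
  nC <- cumC[starts + window + 1L] - cumC[starts + 1L]
  nG <- cumG[starts + window + 1L] - cumG[starts + 1L]
  # CG dinucleotides fully inside the window: starts at window offsets 0..W-2
  nCG <- cumCG[starts + window] - cumCG[starts + 1L]

  gc <- (nC + nG) / window
  obs_exp <- ifelse(nC > 0 & nG > 0, nCG * window / (nC * nG), 0)
  hit <- gc >= min_gc & obs_exp >= min_obs_exp
  if (!any(hit)) {
    return(data.frame(start = integer(), end = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric()))
  }

  # merge qualifying windows that overlap or touch
  ir <- IRanges::reduce(IRanges::IRanges(starts[hit] + 1L, starts[hit] + window))
  s <- IRanges::start(ir) - 1L
  e <- IRanges::end(ir)
  keep <- (e - s) >= min_len
  s <- s[keep]; e <- e[keep]

  gc_frac <- obs_exp_isl <- numeric(length(s))
  for (i in seq_along(s)) {
    Wl <- e[i] - s[i]
    c_i <- cumC[e[i] + 1L] - cumC[s[i] + 1L]
    g_i <- cumG[e[i] + 1L] - cumG[s[i] + 1L]
    cg_i <- cumCG[e[i]] - cumCG[s[i] + 1L]
    gc_frac[i] <- (c_i + g_i) / Wl
    obs_exp_isl[i] <- if (c_i > 0 && g_i > 0) cg_i * Wl / (c_i * g_i) else 0
  }
  data.frame(start = s, end = e, gc_fraction = gc_frac,
             obs_exp_cpg = obs_exp_isl)
}

#' Apply the promoter exclusion filters
#'
#' Rejection reasons are assigned with a fixed precedence:
#' `off_scaffold` (from extraction) -> `overlaps_gap` (window shares >= 1 base
#' with an N run) -> `short_scaffold` (scaffold not strictly longer than
#' `min_scaffold_len`) -> `cpg_contamination` (scaffold carries a merged CpG
#' island of at least 10 kb) -> `overlaps_promoter` (window shares any base
#' with another extracted promoter; both members of an overlapping pair are
#' rejected). The retained set is mutually non-overlapping.
#'
#' @param promoters promoter data.frame from [extract_core_promoters()]
#' @param scaffolds named character vector of scaffold sequences
#' @param min_scaffold_len scaffolds must be strictly longer than this
#'   (default 10 kb)
#' @param cpg_islands optional precomputed island table per scaffold: a named
#'   list of data.frames from [detect_cpg_islands()]; computed internally
#'   when `NULL`
#' @return `promoters` with `status`/`rejection_reason` finalised
#' @export
filter_promoters <- function(promoters, scaffolds, min_scaffold_len = 10000L,
                             cpg_islands = NULL) {
  p <- promoters
  used_scaffolds <- unique(p$scaffold_id[p$status == "retained"])

  gaps <- lapply(scaffolds[used_scaffolds], detect_gaps)
  if (is.null(cpg_islands)) {
    cpg_islands <- lapply(scaffolds[used_scaffolds], detect_cpg_islands,
                          min_len = 10000L)
  }
  contaminated <- names(cpg_islands)[vapply(cpg_islands, nrow, 0L) > 0]

  live <- which(p$status == "retained")
  for (i in live) {
    sc <- p$scaffold_id[i]
    g <- gaps[[sc]]
    if (!is.null(g) && nrow(g) > 0 &&
        any(p$start[i] < g$end & p$end[i] > g$start)) {
      p$status[i] <- "rejected"
      p$rejection_reason[i] <- "overlaps_gap"
    } else if (nchar(scaffolds[[sc]]) <= min_scaffold_len) {
      p$status[i] <- "rejected"
      p$rejection_reason[i] <- "short_scaffold"
    } else if (sc %in% contaminated) {
      p$status[i] <- "rejected"
      p$rejection_reason[i] <- "cpg_contamination"
    }
  }

  # overlap exclusion among all extracted (in-bounds) promoters, strand-blind
  extracted <- which(!(p$rejection_reason %in% c("no_5utr", "off_scaffold")) |
                       is.na(p$rejection_reason))
  if (length(extracted) > 1) {
    ir <- GenomicRanges::GRanges(
      p$scaffold_id[extracted],
      IRanges::IRanges(p$start[extracted] + 1L, p$end[extracted])
    )
    hits <- GenomicRanges::findOverlaps(ir, drop.self = TRUE,
                                        drop.redundant = FALSE)
    clash <- extracted[unique(S4Vectors::queryHits(hits))]
    both <- clash[p$status[clash] == "retained"]
    p$status[both] <- "rejected"
    p$rejection_reason[both] <- "overlaps_promoter"
  }
  p
}
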