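#' Tile scaffolds into fixed non-overlapping windows
#'
#' Scaffolds shorter than `min_scaffold_len` are excluded, and only full
#' windows are kept (a trailing remainder shorter than `window_size` is
#' dropped), so every window measures exactly "genes per `window_size`".
#'
#' @param scaffolds named character vector of scaffold sequences, or a named
#'   integer vector of scaffold lengths
#' @param window_size window width in bp (default 50 kb)
#' @param min_scaffold_len minimum scaffold length to tile (default =
#'   `window_size`)
#' @return data.frame with `scaffold_id`, `start`, `end` (0-based half-open)
#'   and `tss_count` initialised to 0
#' @export
tile_windows <- function(scaffolds, window_size = 50000L,
                         min_scaffold_len = window_size) {
  stopifnot(window_size > 0)
  lens <- if (is.character(scaffolds)) nchar(scaffolds) else scaffolds
  lens <- lens[lens >= min_scaffold_len]
  if (length(lens) == 0) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), tss_count = integer(),
                      stringsAsFactors = FALSE))
  }
  nwin <- lens %/% window_size
  data.frame(
    scaffold_id = rep(names(lens), nwin),
    start = as.integer(unlist(lapply(nwin, function(k)
      (seq_len(k) - 1L) * window_size), use.names = FALSE)),
    end = as.integer(unlist(lapply(nwin, function(k)
      seq_len(k) * window_size), use.names = FALSE)),
    tss_count = 0L,
    stringsAsFactors = FALSE
  )
}

#' Count TSSs per genomic window
#'
#' A TSS at position `p` is counted in the unique window with
#' `start <= p < end`.
#'
#' @param windows window data.frame from [tile_windows()]
#' @param tss_records TSS data.frame from [derive_tss()]
#' @return `windows` with `tss_count` filled in
#' @export
count_tss <- function(windows, tss_records) {
  if (nrow(windows) == 0) return(windows)
  wgr <- GenomicRanges::GRanges(
    windows$scaffold_id,
    IRanges::IRanges(windows$start + 1L, windows$end)
  )
  if (nrow(tss_records) == 0) {
    windows$tss_count <- 0L
    return(windows)
  }
  tgr <- GenomicRanges::GRanges(
    tss_records$scaffold_id,
    IRanges::IRanges(tss_records$position + 1L, width = 1L)
  )
  # TSSs on untiled scaffolds simply count nowhere; silence the seqlevel
  # mismatch chatter that situation triggers
  windows$tss_count <- suppressWarnings(
    GenomicRanges::countOverlaps(wgr, tgr))
  windows
}

#' Summary gene-density statistics for a genome
#'
#' Computes the per-genome summary used for cross-species gene-density
#' comparison: genome size (non-mitochondrial bases), gene count, genes per
#' Mb, median TSS count per window, gene-desert windows (windows with no TSS)
#' and their percentage of tiled windows, %AT over non-N bases, and intron
#' statistics.
#'
#' @param scaffolds named character vector of scaffold sequences
#' @param genes gene-model data.frame
#' @param windows counted windows from [count_tss()]
#' @param mito_pattern regex identifying mitochondrial scaffold ids to
#'   exclude from the size and composition figures
#' @return one-row data.frame with columns `genome_size_mb`, `n_genes`,
#'   `genes_per_mb`, `median_per_window`, `n_desert_windows`, `pct_desert`,
#'   `pct_at`, `mean_introns_per_gene`, `mean_intron_size_bp`
#' @export
density_summary <- function(scaffolds, genes, windows,
                            mito_pattern = "MT|mito|chrM") {
  if (nrow(windows) == 0) .stopf("empty window list")
  keep <- !grepl(mito_pattern, names(scaffolds))
  sc <- scaffolds[keep]
  genome_size_mb <- sum(nchar(sc)) / 1e6
  g <- genes[genes$scaffold_id %in% names(sc), , drop = FALSE]
  n_genes <- nrow(g)

  comp <- .base_counts(sc)
  acgt <- sum(comp[c("A", "C", "G", "T")])
  pct_at <- 100 * sum(comp[c("A", "T")]) / acgt

  n_desert <- sum(windows$tss_count == 0)
  istats <- intron_stats(g)

  data.frame(
    genome_size_mb = genome_size_mb,
    n_genes = n_genes,
    genes_per_mb = genes_per_mb(n_genes, genome_size_mb),
    median_per_window = stats::median(windows$tss_count),
    n_desert_windows = n_desert,
    pct_desert = 100 * n_desert / nrow(windows),
    pct_at = pct_at,
    mean_introns_per_gene = istats[["mean_introns_per_gene"]],
    mean_intron_size_bp = istats[["mean_intron_size_bp"]]
  )
}

.base_counts <- function(scaffolds) {
  m <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(scaffolds))
  counts <- colSums(m)
  counts[c("A", "C", "G", "T", "N")]
}

#' Intron statistics over a gene set
#'
#' Intron count per gene is `max(0, n_exons - 1)`; intron sizes are the gaps
#' between consecutive exons. Genes without exon structure contribute 0
#' introns. When the gene set has no introns at all, the mean intron size is
#' reported as 0 with a warning.
#'
#' @param genes gene-model data.frame
#' @return named numeric vector `mean_introns_per_gene`, `mean_intron_size_bp`
#' @export
intron_stats <- function(genes) {
  if (nrow(genes) == 0) {
    return(c(mean_introns_per_gene = 0, mean_intron_size_bp = 0))
  }
  validate_gene_models(genes)
  n_introns <- integer(nrow(genes))
  sizes <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (is.null(ex) || nrow(ex) < 2) next
    n_introns[i] <- nrow(ex) - 1L
    sizes[[i]] <- ex[-1, 1] - ex[-nrow(ex), 2]
  }
  all_sizes <- unlist(sizes, use.names = FALSE)
  if (length(all_sizes) == 0) {
    .warnf("gene set contains no introns; mean intron size reported as 0")
    mean_size <- 0
  } else {
    mean_size <- mean(all_sizes)
  }
  c(mean_introns_per_gene = mean(n_introns),
    mean_intron_size_bp = mean_size)
}

#' Drop mitochondrial scaffolds
#'
#' @param scaffolds named character vector of scaffold sequences
#' @param mito_pattern regex matched against scaffold ids
#' @return `scaffolds` without matching entries
#' @export
filter_mitochondrial <- function(scaffolds, mito_pattern = "MT|mito|chrM") {
  scaffolds[!grepl(mito_pattern, names(scaffolds))]
}
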