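#' Adjacent gene-pair regions on each scaffold
#'
#' Genes are ordered by `tx_start` (ties broken by `tx_end`) per scaffold and
#' every consecutive pair forms one region. Categories follow the strand
#' configuration of the (left, right) genes: `head_to_head` for `(-,+)`
#' (divergent 5' ends), `tail_to_tail` for `(+,-)` (convergent 3' ends), and
#' `head_to_tail` otherwise (co-oriented). `gap_bp` is the intergenic length
#' (`0` when the genes overlap) and `tss_distance_bp` is the TSS-to-TSS
#' distance, reported for head-to-head pairs.
#'
#' @param genes gene-model data.frame
#' @return data.frame with one row per consecutive pair: `scaffold_id`,
#'   `left_gene_id`, `right_gene_id`, `category`, `overlapping`, `gap_bp`,
#'   `tss_distance_bp`
#' @export
adjacent_pairs <- function(genes) {
  empty <- data.frame(
    scaffold_id = character(), left_gene_id = character(),
    right_gene_id = character(), category = character(),
    overlapping = logical(), gap_bp = integer(),
    tss_distance_bp = integer(), stringsAsFactors = FALSE
  )
  if (nrow(genes) < 2) return(empty)
  ord <- order(genes$scaffold_id, genes$tx_start, genes$tx_end)
  g <- genes[ord, , drop = FALSE]
  same <- g$scaffold_id[-nrow(g)] == g$scaffold_id[-1]
  if (!any(same)) return(empty)
  li <- which(same)
  ri <- li + 1L

  ls <- g$strand[li]; rs <- g$strand[ri]
  category <- ifelse(ls == "-" & rs == "+", "head_to_head",
              ifelse(ls == "+" & rs == "-", "tail_to_tail", "head_to_tail"))
  overlapping <- g$tx_end[li] > g$tx_start[ri]
  gap_bp <- pmax(0L, g$tx_start[ri] - g$tx_end[li])
  tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L)
  tssd <- ifelse(category == "head_to_head", abs(tss[li] - tss[ri]),
                 NA_integer_)

  data.frame(
    scaffold_id = g$scaffold_id[li],
    left_gene_id = g$gene_id[li],
    right_gene_id = g$gene_id[ri],
    category = category,
    overlapping = overlapping,
    gap_bp = as.integer(gap_bp),
    tss_distance_bp = as.integer(tssd),
    stringsAsFactors = FALSE
  )
}

#' Gene-orientation summary table
#'
#' Tallies adjacent-pair regions per orientation category into overlapping,
#' non-overlapping, and non-overlapping-but-near (intergenic gap <
#' `near_threshold`) counts, then derives the two percentage columns via
#' [orientation_table_from_counts()].
#'
#' @param pairs data.frame from [adjacent_pairs()]
#' @param near_threshold "near" gap cutoff in bp (default 1 kb)
#' @return summary data.frame (one row per category plus a TOTAL row)
#' @export
orientation_table <- function(pairs, near_threshold = 1000L) {
  if (nrow(pairs) == 0) .stopf("empty pair list")
  cats <- c("head_to_head", "tail_to_tail", "head_to_tail")
  f <- factor(pairs$category, levels = cats)
  counts <- data.frame(
    category = cats,
    overlapping = as.integer(table(f[pairs$overlapping])),
    not_overlapping = as.integer(table(f[!pairs$overlapping])),
    near = as.integer(table(f[!pairs$overlapping &
                                pairs$gap_bp < near_threshold])),
    stringsAsFactors = FALSE
  )
  orientation_table_from_counts(counts)
}

#' Orientation percentages from category counts
#'
#' Given per-category counts of overlapping, non-overlapping and
#' non-overlapping-near regions, computes each category's share of all
#' regions, `(overlapping + not_overlapping) / grand total`, and its share of
#' close regions, `(overlapping + near) / (total overlapping + total near)`,
#' both as half-up one-decimal percentages, and appends a TOTAL row carrying
#' the two denominators.
#'
#' @param counts data.frame with columns `category`, `overlapping`,
#'   `not_overlapping`, `near`
#' @return `counts` with `pct_regions` and `pct_regions_near` columns and a
#'   TOTAL row
#' @export
orientation_table_from_counts <- function(counts) {
  grand_total <- sum(counts$overlapping) + sum(counts$not_overlapping)
  near_total <- sum(counts$overlapping) + sum(counts$near)
  out <- counts
  out$pct_regions <-
    fraction_pct(counts$overlapping + counts$not_overlapping, grand_total)
  out$pct_regions_near <-
    fraction_pct(counts$overlapping + counts$near, near_total)
  total <- data.frame(
    category = "TOTAL",
    overlapping = sum(counts$overlapping),
    not_overlapping = sum(counts$not_overlapping),
    near = sum(counts$near),
    pct_regions = grand_total,
    pct_regions_near = near_total,
    stringsAsFactors = FALSE
  )
  rbind(out, total)
}

#' Classify promoter directionality
#'
#' A head-to-head adjacent gene pair whose TSSs are at most `near_threshold`
#' apart delimits a (possibly) bidirectional promoter region. If both genes of
#' such a pair have retained promoters, both are `bidirectional`; if exactly
#' one does (e.g. the partner lacks an annotated 5' UTR or was filtered), the
#' retained one is `putative_bidirectional`; every other retained promoter is
#' `unidirectional`. The three classes partition the retained promoters.
#'
#' @param retained_promoters promoter data.frame (rows with
#'   `status == "retained"` are classified; others ignored)
#' @param genes gene-model data.frame (all genes, used to form adjacent pairs)
#' @param near_threshold TSS-to-TSS distance cutoff in bp, inclusive
#'   (default 1 kb)
#' @return data.frame `promoter_id` (gene id), `class`
#' @export
classify_directionality <- function(retained_promoters, genes,
                                    near_threshold = 1000L) {
  ret <- retained_promoters[retained_promoters$status == "retained", ,
                            drop = FALSE]
  cls <- stats::setNames(rep("unidirectional", nrow(ret)), ret$gene_id)
  pairs <- adjacent_pairs(genes)
  hh <- pairs[pairs$category == "head_to_head" &
                !is.na(pairs$tss_distance_bp) &
                pairs$tss_distance_bp <= near_threshold, , drop = FALSE]
  for (i in seq_len(nrow(hh))) {
    members <- c(hh$left_gene_id[i], hh$right_gene_id[i])
    present <- members[members %in% names(cls)]
    if (length(present) == 2) {
      cls[present] <- "bidirectional"
    } else if (length(present) == 1) {
      cls[present] <- "putative_bidirectional"
    }
  }
  data.frame(promoter_id = names(cls), class = unname(cls),
             stringsAsFactors = FALSE)
}
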