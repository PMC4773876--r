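#' Canonical motif constructors
#'
#' Convenience constructors for the motifs the directionality analysis uses:
#' the vertebrate polyadenylation-signal consensus (AWUAAA, DNA form AWTAAA),
#' a GC-box (Sp1-like) consensus and its reverse complement, a TATA-box
#' consensus, and a synthetic 9-column splice-donor PFM with the invariant GT
#' dinucleotide at columns 4-5 (a stand-in for a database donor matrix, which
#' users can supply instead via [read_jaspar_pfm()] / [read_meme_motifs()]).
#'
#' @param background,score_threshold passed to [motif_model()]
#' @return a `motif_model`
#' @name canonical_motifs
NULL

#' @rdname canonical_motifs
#' @export
pas_motif <- function() {
  motif_model("PAS", consensus = "AWTAAA")
}

#' @rdname canonical_motifs
#' @export
gcbox_motif <- function() {
  motif_model("Sp1_GCbox", consensus = "GGGGCGGGG")
}

#' @rdname canonical_motifs
#' @export
gcbox_rc_motif <- function() {
  motif_model("Sp1rc", consensus = "CCCCGCCCC")
}

#' @rdname canonical_motifs
#' @export
tata_motif <- function() {
  motif_model("TATA", consensus = "TATAWAWR")
}

#' @rdname canonical_motifs
#' @export
synthetic_donor_pfm <- function() {
  # consensus MAG|GTRAGT; columns 4-5 are the invariant GT
  counts <- rbind(
    A = c(30, 60, 10,  0,  0, 50, 70, 10,  5),
    C = c(35, 10,  5,  0,  0,  2,  5,  5,  5),
    G = c(20, 20, 80, 100,  0, 45, 15, 80,  5),
    T = c(15, 10,  5,  0, 100,  3, 10,  5, 85)
  )
  counts
}

#' @rdname canonical_motifs
#' @export
donor_motif <- function(background = rep(0.25, 4), score_threshold = 0.8) {
  motif_model("SS5_donor_synthetic", pfm = synthetic_donor_pfm(),
              background = background, score_threshold = score_threshold)
}

# directional flank sequence for one anchor, read 5'->3' away from the
# anchor; NA if truncated by a scaffold end.
# sense_downstream: offsets +1..+span on the coding strand.
# antisense_upstream: offsets -1..-span on the template strand (i.e. the
# reverse complement of the region upstream of the anchor, read away from it).
.flank_seq <- function(genome, scaffold_id, position, strand, direction,
                       span) {
  L <- nchar(genome[[scaffold_id]])
  if (strand == "+") {
    if (direction == "sense_downstream") {
      s <- position + 1L; e <- position + span
      if (e > L - 1L) return(NA_character_)
      substr(genome[[scaffold_id]], s + 1L, e + 1L)
    } else {
      s <- position - span; e <- position - 1L
      if (s < 0L) return(NA_character_)
      revcomp(substr(genome[[scaffold_id]], s + 1L, e + 1L))
    }
  } else {
    if (direction == "sense_downstream") {
      s <- position - span; e <- position - 1L
      if (s < 0L) return(NA_character_)
      revcomp(substr(genome[[scaffold_id]], s + 1L, e + 1L))
    } else {
      s <- position + 1L; e <- position + span
      if (e > L - 1L) return(NA_character_)
      substr(genome[[scaffold_id]], s + 1L, e + 1L)
    }
  }
}

#' Cumulative motif frequency away from anchors
#'
#' The U1-PAS axis statistic: for each anchor (typically a TSS), the flank of
#' `span` bp starting at offset +1 downstream on the coding strand
#' (`"sense_downstream"`) or at offset -1 upstream on the template strand
#' (`"antisense_upstream"`, read away from the anchor) is scanned for
#' same-strand motif matches. Hits are binned by the distance of their
#' 5'-most base from the anchor (bin `b`, 0-based, covers distances
#' `[bin_size*b + 1, bin_size*(b+1)]`), the per-bin frequency is hits per bin
#' divided by the number of anchors, and the cumulative profile is its
#' running sum with increasing distance. Anchors with truncated flanks are
#' dropped and counted in `n_dropped`. All hits are counted (not at most one
#' per bin per anchor), so profile mass equals total hits / anchors.
#'
#' @param anchors data.frame with `scaffold_id`, `position`, `strand`
#' @param genome named character vector of scaffold sequences
#' @param motif `motif_model` (e.g. [pas_motif()] or a splice-donor PWM)
#' @param direction `"sense_downstream"` or `"antisense_upstream"`
#' @param span flank length in bp
#' @param bin_size bin width in bp
#' @return object of class `cumulative_profile`: list with `motif_name`,
#'   `direction`, `span`, `bin_size`, `per_bin_frequency`, `cumulative`,
#'   `n_anchors`, `n_dropped`
#' @export
cumulative_motif_frequency <- function(anchors, genome, motif,
                                       direction = c("sense_downstream",
                                                     "antisense_upstream"),
                                       span = 500L, bin_size = 10L) {
  direction <- match.arg(direction)
  nbin <- as.integer(span / bin_size)
  counts <- integer(nbin)
  n_used <- 0L
  n_dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    fs <- .flank_seq(genome, anchors$scaffold_id[i], anchors$position[i],
                     anchors$strand[i], direction, span)
    if (is.na(fs)) {
      n_dropped <- n_dropped + 1L
      next
    }
    n_used <- n_used + 1L
    h <- if (motif$kind == "pwm") {
      scan_pwm(fs, motif, "sense_only")
    } else {
      scan_iupac(fs, motif, "sense_only")
    }
    if (nrow(h)) {
      counts <- counts + tabulate(h$start %/% bin_size + 1L, nbins = nbin)
    }
  }
  if (n_used == 0) .stopf("no anchors with complete flanks")
  per_bin <- counts / n_used
  cumulative <- cumsum(per_bin)
  stopifnot(!is.unsorted(cumulative))
  structure(list(
    motif_name = motif$name, direction = direction, span = span,
    bin_size = bin_size, per_bin_frequency = per_bin,
    cumulative = cumulative, n_anchors = n_used, n_dropped = n_dropped
  ), class = "cumulative_profile")
}

#' @export
print.cumulative_profile <- function(x, ...) {
  cat(sprintf("<cumulative_profile %s %s: %d anchors (%d dropped), final %.4f>\n",
              x$motif_name, x$direction, x$n_anchors, x$n_dropped,
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Cumulative motif frequency anchored on motif hits
#'
#' Re-anchors the cumulative profile on motif occurrences instead of TSSs
#' (e.g. on GC-box hits found near TSSs): each hit's 5'-most genomic base,
#' read with its anchor's strand, becomes a new anchor and the computation is
#' identical to [cumulative_motif_frequency()].
#'
#' @param hits hit data.frame from [window_hits()] (needs `scaffold_id`,
#'   `genomic_pos`, `anchor_strand`), or any data.frame with `scaffold_id`,
#'   `position`, `strand`
#' @inheritParams cumulative_motif_frequency
#' @return a `cumulative_profile`
#' @export
anchored_on_motif <- function(hits, genome, motif,
                              direction = c("sense_downstream",
                                            "antisense_upstream"),
                              span = 500L, bin_size = 10L) {
  if (nrow(hits) == 0) .stopf("empty hit set")
  anchors <- if (all(c("genomic_pos", "anchor_strand") %in% names(hits))) {
    data.frame(scaffold_id = hits$scaffold_id,
               position = hits$genomic_pos,
               strand = hits$anchor_strand,
               stringsAsFactors = FALSE)
  } else {
    hits[, c("scaffold_id", "position", "strand")]
  }
  cumulative_motif_frequency(anchors, genome, motif, direction, span,
                             bin_size)
}
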