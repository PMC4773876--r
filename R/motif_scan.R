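#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide classes; a sequence N never matches any class (windows
# containing gap characters are not scoreable)
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 4 x w logical matrix: allowed[base, j]
.iupac_allowed <- function(consensus) {
  cls <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- setdiff(cls, names(.IUPAC))
  if (length(bad)) .stopf("invalid IUPAC character(s): %s",
                          paste(unique(bad), collapse = ""))
  vapply(cls, function(k) c("A", "C", "G", "T") %in% .IUPAC[[k]],
         logical(4))
}

#' Construct a motif model
#'
#' A motif is either a position frequency matrix (PFM) of per-column base
#' counts, scanned through its log-odds position weight matrix (PWM), or an
#' IUPAC consensus string matched exactly per position (`U` is treated as
#' `T`). The PWM score threshold is expressed as a fraction of the motif's
#' maximum achievable log-odds score.
#'
#' @param name motif name
#' @param pfm 4 x w non-negative count matrix with rows A, C, G, T (PWM kind)
#' @param consensus IUPAC string (consensus kind); exactly one of `pfm`/
#'   `consensus` must be given
#' @param background base frequencies (A, C, G, T), strictly positive,
#'   summing to 1; defaults to uniform, and pipeline callers typically pass
#'   the scanned genome's mononucleotide composition
#' @param pseudocount pseudocount mass added per column (split by background)
#' @param score_threshold fraction of the maximum log-odds score a window
#'   must reach to be a hit (PWM kind)
#' @return object of class `motif_model`
#' @export
motif_model <- function(name, pfm = NULL, consensus = NULL,
                        background = rep(0.25, 4), pseudocount = 0.25,
                        score_threshold = 0.8) {
  if (is.null(pfm) == is.null(consensus)) {
    .stopf("give exactly one of pfm or consensus")
  }
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount >= 0,
            score_threshold >= 0, score_threshold <= 1)
  m <- list(name = name,
            kind = if (is.null(pfm)) "iupac" else "pwm",
            pfm = pfm,
            consensus = if (!is.null(consensus)) {
              chartr("u", "U", toupper(consensus))
            },
            background = background, pseudocount = pseudocount,
            score_threshold = score_threshold)
  if (m$kind == "pwm") {
    stopifnot(is.matrix(pfm), nrow(pfm) == 4, ncol(pfm) >= 1, all(pfm >= 0))
    rownames(m$pfm) <- c("A", "C", "G", "T")
    m$pwm <- build_pwm(m$pfm, background, pseudocount)
    m$width <- ncol(pfm)
  } else {
    m$consensus <- chartr("U", "T", m$consensus)
    m$allowed <- .iupac_allowed(m$consensus)
    m$width <- nchar(m$consensus)
  }
  class(m) <- "motif_model"
  m
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model %s: %s, width %d>\n", x$name, x$kind, x$width))
  invisible(x)
}

#' Log-odds position weight matrix from a count matrix
#'
#' `score(b, j) = log2(((pfm[b,j] + pseudocount * bg[b]) / (N_j + pseudocount))
#' / bg[b])` with `N_j` the column count sum. The matrix carries the maximum
#' achievable score (sum of column maxima) as attribute `max_score`.
#'
#' @param pfm 4 x w non-negative count matrix, rows A, C, G, T
#' @param background base frequencies
#' @param pseudocount pseudocount mass per column
#' @return 4 x w log-odds matrix with attribute `max_score`
#' @export
build_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.25) {
  stopifnot(is.matrix(pfm), nrow(pfm) == 4, all(pfm >= 0), pseudocount >= 0)
  nj <- colSums(pfm)
  if (pseudocount == 0 && any(nj == 0)) {
    .stopf("all-zero PFM column without pseudocount")
  }
  p <- sweep(pfm + pseudocount * background, 2, nj + pseudocount, "/")
  pwm <- log2(p / background)
  rownames(pwm) <- c("A", "C", "G", "T")
  attr(pwm, "max_score") <- sum(apply(pwm, 2, max))
  pwm
}

# core window scorer: for encoded sequence, return per-start log-odds sums;
# windows containing N score -Inf
.pwm_window_scores <- function(code, pwm) {
  w <- ncol(pwm)
  P <- length(code) - w + 1L
  if (P < 1) return(numeric(0))
  scores <- numeric(P)
  nas <- logical(P)
  for (j in seq_len(w)) {
    cj <- code[j:(j + P - 1L)]
    na <- is.na(cj)
    nas <- nas | na
    cj[na] <- 1L
    scores <- scores + pwm[cj + (j - 1L) * 4L]
  }
  scores[nas] <- -Inf
  scores
}

.iupac_window_hits <- function(code, allowed) {
  w <- ncol(allowed)
  P <- length(code) - w + 1L
  if (P < 1) return(logical(0))
  ok <- rep(TRUE, P)
  for (j in seq_len(w)) {
    cj <- code[j:(j + P - 1L)]
    v <- allowed[cbind(cj, j)]
    v[is.na(v)] <- FALSE
    ok <- ok & v
  }
  ok
}

.hit_frame <- function(start, strand, score, site) {
  data.frame(start = as.integer(start), strand = strand, score = score,
             site = site, stringsAsFactors = FALSE)
}

# substring() rejects zero-length first/last; sites of empty hit sets must
# still be character(0)
.sites <- function(text, first, last) {
  if (length(first) == 0) return(character(0))
  substring(text, first, last)
}

#' Scan a sequence with an IUPAC consensus
#'
#' Reports a hit at every position where each base falls in the consensus
#' class; windows containing `N` never match. In `"both"` mode the reverse
#' complement is scanned as well and antisense hits are reported at the
#' 5'-most coordinate of the site on the given (sense) sequence;
#' `"sense_only"` mirrors single-strand scanning.
#'
#' @param sequence one DNA string
#' @param consensus IUPAC consensus (or a `motif_model` of kind iupac)
#' @param strand_mode `"sense_only"` or `"both"`
#' @return data.frame `start` (0-based position of the site's 5'-most base on
#'   the scanned sequence), `strand` (`"sense"`/`"antisense"`), `score`
#'   (`NA` for consensus matches), `site` (the matched substring as read on
#'   the matching strand)
#' @export
scan_iupac <- function(sequence, consensus,
                       strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  allowed <- if (inherits(consensus, "motif_model")) {
    stopifnot(consensus$kind == "iupac")
    consensus$allowed
  } else {
    .iupac_allowed(chartr("Uu", "TT", consensus))
  }
  w <- ncol(allowed)
  code <- .encode_dna(sequence)
  L <- length(code)
  hits <- which(.iupac_window_hits(code, allowed)) - 1L
  out <- .hit_frame(hits, rep("sense", length(hits)), rep(NA_real_, length(hits)),
                    .sites(sequence, hits + 1L, hits + w))
  if (strand_mode == "both") {
    rc <- revcomp(sequence)
    rhits <- which(.iupac_window_hits(.encode_dna(rc), allowed)) - 1L
    sense_start <- L - w - rhits
    out <- rbind(out, .hit_frame(sense_start,
                                 rep("antisense", length(rhits)), rep(NA_real_, length(rhits)),
                                 .sites(rc, rhits + 1L, rhits + w)))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a sequence with a log-odds PWM
#'
#' Every window scoring at least `score_threshold * max_score` is reported;
#' overlapping and tied hits are all kept (no greedy masking). Windows
#' containing `N` never pass (their score is -Inf).
#'
#' @param sequence one DNA string
#' @param motif a `motif_model` of kind pwm
#' @param strand_mode `"sense_only"` or `"both"`
#' @return hit data.frame as in [scan_iupac()], with log-odds `score`
#' @export
scan_pwm <- function(sequence, motif, strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(motif, "motif_model"), motif$kind == "pwm")
  pwm <- motif$pwm
  w <- ncol(pwm)
  thr <- motif$score_threshold * attr(pwm, "max_score")
  code <- .encode_dna(sequence)
  L <- length(code)
  sc <- .pwm_window_scores(code, pwm)
  hits <- which(sc >= thr)
  out <- .hit_frame(hits - 1L, rep("sense", length(hits)), sc[hits],
                    .sites(sequence, hits, hits + w - 1L))
  if (strand_mode == "both") {
    rc <- revcomp(sequence)
    rsc <- .pwm_window_scores(.encode_dna(rc), pwm)
    rhits <- which(rsc >= thr)
    sense_start <- L - w - (rhits - 1L)
    out <- rbind(out, .hit_frame(sense_start,
                                 rep("antisense", length(rhits)),
                                 rsc[rhits],
                                 .sites(rc, rhits, rhits + w - 1L)))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a motif over anchored windows in genomic coordinates
#'
#' For every anchor (a TSS or other genomic position with a reading strand),
#' extracts the sense-oriented window `[window[1], window[2])` relative to
#' the anchor, scans it with the motif, and reports hits with offsets
#' relative to the anchor (anchor = 0; the offset is the position of the
#' site's 5'-most base on the anchor's sense strand). Anchors whose window is
#' incomplete (runs off the scaffold) or contains gap bases (`N`) are
#' excluded.
#'
#' @param anchors data.frame with `scaffold_id`, `position` (0-based),
#'   `strand`
#' @param genome named character vector of scaffold sequences
#' @param motif `motif_model`
#' @param window integer pair, half-open offsets around the anchor
#' @param strand_mode `"sense_only"` or `"both"`
#' @return list with `hits` (data.frame `anchor`, `offset`, `strand`,
#'   `score`, `site`, `scaffold_id`, `genomic_pos`, `anchor_strand`) and
#'   `n_regions`, the number of anchors with complete gap-free windows
#' @export
window_hits <- function(anchors, genome, motif, window = c(-400L, 100L),
                        strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(window[1] < window[2])
  seqs <- .anchor_windows(anchors, genome, window)
  keep <- which(!is.na(seqs))
  res <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    h <- if (motif$kind == "pwm") {
      scan_pwm(seqs[i], motif, strand_mode)
    } else {
      scan_iupac(seqs[i], motif, strand_mode)
    }
    if (nrow(h) == 0) next
    offset <- window[1] + h$start
    gpos <- if (anchors$strand[i] == "+") {
      anchors$position[i] + offset
    } else {
      anchors$position[i] - offset
    }
    res[[k]] <- data.frame(
      anchor = i, offset = as.integer(offset), strand = h$strand,
      score = h$score, site = h$site,
      scaffold_id = anchors$scaffold_id[i],
      genomic_pos = as.integer(gpos),
      anchor_strand = anchors$strand[i],
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(hits)) {
    hits <- data.frame(anchor = integer(), offset = integer(),
                       strand = character(), score = numeric(),
                       site = character(), scaffold_id = character(),
                       genomic_pos = integer(), anchor_strand = character(),
                       stringsAsFactors = FALSE)
  }
  list(hits = hits, n_regions = length(keep))
}

# sense-oriented window sequences per anchor; NA when incomplete or gapped
.anchor_windows <- function(anchors, genome, window) {
  n <- nrow(anchors)
  pos <- anchors$position
  plus <- anchors$strand == "+"
  start <- ifelse(plus, pos + window[1], pos - window[2] + 1L)
  end <- ifelse(plus, pos + window[2], pos - window[1] + 1L)
  sc_len <- nchar(genome)[anchors$scaffold_id]
  ok <- !is.na(sc_len) & start >= 0L & end <= sc_len
  seqs <- rep(NA_character_, n)
  if (any(ok)) {
    raw <- substr(genome[anchors$scaffold_id[ok]], start[ok] + 1L, end[ok])
    neg <- !plus[ok]
    raw[neg] <- revcomp(raw[neg])
    raw[grepl("N", raw, fixed = TRUE)] <- NA_character_
    seqs[ok] <- raw
  }
  seqs
}

#' Positional motif-frequency profile around anchors
#'
#' Bins motif hits by their offset relative to the anchor into adjacent
#' `bin_size` bins across `window` (bin `b` covers
#' `[window[1] + bin_size*b, window[1] + bin_size*(b+1))`; with the defaults,
#' 50 bins from -400 to +100 with the anchor at offset 0 in bin `[0,10)`).
#' The frequency is hits per bin divided by the number of complete regions.
#'
#' @inheritParams window_hits
#' @param bin_size bin width in bp
#' @return object of class `bin_profile`: list with `motif_name`, `window`,
#'   `bin_size`, `bin_start`, `frequency`, `n_regions`, `hits`
#' @export
positional_profile <- function(anchors, genome, motif,
                               window = c(-400L, 100L), bin_size = 10L,
                               strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  wh <- window_hits(anchors, genome, motif, window, strand_mode)
  if (wh$n_regions == 0) .stopf("no anchors with complete gap-free windows")
  nbin <- as.integer((window[2] - window[1]) / bin_size)
  bin <- (wh$hits$offset - window[1]) %/% bin_size
  counts <- tabulate(bin + 1L, nbins = nbin)
  structure(list(
    motif_name = motif$name,
    window = window,
    bin_size = bin_size,
    bin_start = window[1] + bin_size * (seq_len(nbin) - 1L),
    frequency = counts / wh$n_regions,
    n_regions = wh$n_regions,
    hits = wh$hits
  ), class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("<bin_profile %s: %d bins of %d bp over [%d,%d), %d regions, %d hits>\n",
              x$motif_name, length(x$frequency), x$bin_size, x$window[1],
              x$window[2], x$n_regions, nrow(x$hits)))
  invisible(x)
}

#' Nucleotide and dinucleotide composition around anchors
#'
#' Per-offset base and dinucleotide frequencies over all anchors with
#' complete, gap-free windows. Dinucleotide frequency at offset `o` is the
#' frequency of the pair starting at `o` on the sense strand (so `CG` means
#' C followed by G reading 5'->3' on the coding strand).
#'
#' @inheritParams window_hits
#' @return list with `base` (4 x width matrix of frequencies), `dinuc`
#'   (16 x width-1), `offsets`, `n_regions`
#' @export
composition_profile <- function(anchors, genome, window = c(-150L, 50L)) {
  seqs <- .anchor_windows(anchors, genome, window)
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0) .stopf("no anchors with complete gap-free windows")
  width <- window[2] - window[1]
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = width, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  base_freq <- vapply(seq_len(width), function(j)
    tabulate(match(chars[, j], bases), 4), numeric(4)) / length(seqs)
  rownames(base_freq) <- bases
  din_names <- as.vector(outer(bases, bases, function(a, b) paste0(a, b)))
  dinuc <- vapply(seq_len(width - 1L), function(j)
    tabulate(match(paste0(chars[, j], chars[, j + 1L]), din_names), 16),
    numeric(16)) / length(seqs)
  rownames(dinuc) <- din_names
  list(base = base_freq, dinuc = dinuc,
       offsets = window[1]:(window[2] - 1L), n_regions = length(seqs))
}

#' Read motifs from JASPAR raw PFM files
#'
#' Accepts the raw JASPAR layout: a `>identifier name` header followed by
#' four rows of counts, either bare numbers or in the
#' `A [ 1 2 3 ]` bracket style, in A/C/G/T order.
#'
#' @param path file path
#' @param ... passed to [motif_model()] (background, pseudocount,
#'   score_threshold)
#' @return named list of `motif_model` objects
#' @export
read_jaspar_pfm <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) .stopf("no '>' headers in %s", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4) .stopf("motif block with fewer than 4 rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      .stopf("ragged PFM rows in %s", path)
    }
    pfm <- do.call(rbind, rows)
    nm <- sub("^>\\s*", "", lines[heads[i]])
    nm <- strsplit(nm, "\\s+")[[1]]
    nm <- nm[length(nm)]
    out[[nm]] <- motif_model(nm, pfm = pfm, ...)
  }
  out
}

#' Read motifs from MEME minimal motif format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections;
#' probabilities are converted back to counts using the stated `nsites`
#' (default 20 when absent). A `Background letter frequencies` line, when
#' present, is used as the default scanning background.
#'
#' @param path file path
#' @param background override the file's background frequencies
#' @param ... passed to [motif_model()]
#' @return named list of `motif_model` objects
#' @export
read_meme_motifs <- function(path, background = NULL, ...) {
  lines <- readLines(path)
  bg <- background
  bgi <- grep("^Background letter frequencies", lines)
  if (is.null(bg) && length(bgi)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- unname(vals[c("A", "C", "G", "T")])
  }
  if (is.null(bg)) bg <- rep(0.25, 4)

  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) .stopf("no MOTIF blocks in %s", path)
  out <- list()
  for (s in starts) {
    nm <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr_i <- s + grep("^letter-probability matrix",
                      lines[(s + 1):length(lines)])[1]
    hdr <- lines[hdr_i]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    } else 20
    probs <- do.call(rbind, lapply(lines[(hdr_i + 1):(hdr_i + w)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    pfm <- t(probs) * nsites
    out[[nm]] <- motif_model(nm, pfm = pfm, background = bg, ...)
  }
  out
}
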