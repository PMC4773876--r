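#' Read a genome from FASTA
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` (IUPAC
#' ambiguity codes, soft-mask leftovers) is mapped to `N` with a warning.
#' Soft-masked (lowercase) bases are uppercased and retained, not excluded.
#' Duplicate scaffold identifiers are an error.
#'
#' @param fasta_source path to a (multi-record) FASTA file
#' @return named character vector of scaffold sequences; names are scaffold
#'   ids (FASTA header up to the first whitespace)
#' @export
read_genome <- function(fasta_source) {
  seqs <- Biostrings::readBStringSet(fasta_source)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    .stopf("duplicate scaffold id(s) in %s: %s", fasta_source,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  names(x) <- ids
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    .warnf("non-ACGTN characters in %d scaffold(s) mapped to N", sum(bad))
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of scaffold sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 60)
  invisible(path)
}

.empty_gene_models <- function() {
  data.frame(
    gene_id = character(), scaffold_id = character(), strand = character(),
    tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer(),
    has_annotated_5utr = logical(),
    stringsAsFactors = FALSE
  )
}

.new_gene_models <- function(gene_id, scaffold_id, strand, tx_start, tx_end,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             exons = NULL) {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    scaffold_id = as.character(scaffold_id),
    strand = as.character(strand),
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    cds_start = as.integer(rep_len(cds_start, n)),
    cds_end = as.integer(rep_len(cds_end, n)),
    stringsAsFactors = FALSE
  )
  if (is.null(exons)) exons <- vector("list", n)
  df$exons <- exons
  df$has_annotated_5utr <- .has_utr5(df)
  validate_gene_models(df)
  df
}

# has_annotated_5utr is true iff the sense-strand CDS start lies strictly
# downstream of the TSS (i.e., the transcript has leading untranslated bases)
.has_utr5 <- function(genes) {
  ifelse(
    is.na(genes$cds_start), FALSE,
    ifelse(genes$strand == "+",
           genes$cds_start > genes$tx_start,
           genes$cds_end < genes$tx_end)
  )
}

#' Validate a gene-model table
#'
#' Checks the structural invariants: `tx_start < tx_end`; CDS (when present)
#' contained in the transcript; exons sorted, non-overlapping and inside the
#' transcript.
#'
#' @param genes gene-model data.frame
#' @return `genes`, invisibly; errors on violation
#' @export
validate_gene_models <- function(genes) {
  if (nrow(genes) == 0) return(invisible(genes))
  stopifnot(all(genes$strand %in% c("+", "-")))
  if (any(genes$tx_start >= genes$tx_end)) {
    .stopf("gene model(s) with tx_start >= tx_end")
  }
  has_cds <- !is.na(genes$cds_start)
  if (any(has_cds & (genes$cds_start < genes$tx_start |
                     genes$cds_end > genes$tx_end))) {
    .stopf("CDS outside transcript bounds")
  }
  if (!is.null(genes$exons)) {
    for (i in seq_len(nrow(genes))) {
      ex <- genes$exons[[i]]
      if (is.null(ex) || nrow(ex) == 0) next
      if (is.unsorted(ex[, 1]) || any(ex[-1, 1] < ex[-nrow(ex), 2])) {
        .stopf("gene %s: exons unsorted or overlapping", genes$gene_id[i])
      }
      if (ex[1, 1] < genes$tx_start[i] || ex[nrow(ex), 2] > genes$tx_end[i]) {
        .stopf("gene %s: exons outside transcript", genes$gene_id[i])
      }
    }
  }
  invisible(genes)
}

.coding_biotypes <- c("coding", "protein_coding", "mrna")

#' Read gene models from GFF3 or BED12
#'
#' Internal coordinates are 0-based half-open throughout; GFF3's 1-based
#' closed intervals are converted on read, BED is native. One gene model is
#' produced per transcript (GFF3 `mRNA`/`transcript` features, or one per BED
#' line). When a biotype attribute is present in the GFF3, non-coding records
#' are excluded (the `coding`/`protein_coding` biotype filter).
#'
#' @param annotation_source path to the annotation file
#' @param dialect `"gff3"` or `"bed12"` (BED6 also accepted under `"bed12"`)
#' @return gene-model data.frame with columns `gene_id`, `scaffold_id`,
#'   `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, a list-column
#'   `exons` of two-column matrices (0-based half-open), and
#'   `has_annotated_5utr`
#' @export
read_gene_models <- function(annotation_source, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") .read_gff3_models(annotation_source)
  else .read_bed12_models(annotation_source)
}

# ##sequence-region pragmas ("id start end", 1-based closed)
.gff3_seqlens <- function(path) {
  lines <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(lines) == 0) return(integer(0))
  parts <- strsplit(trimws(lines), "\\s+")
  stats::setNames(
    vapply(parts, function(p) as.integer(p[4]), integer(1)),
    vapply(parts, function(p) p[2], character(1))
  )
}

.read_gff3_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_tx <- type %in% c("mRNA", "transcript")
  if (!any(is_tx)) .stopf("no mRNA/transcript features in %s", path)

  # biotype filter: exclude transcripts whose biotype attribute is non-coding
  bio_cols <- intersect(
    c("biotype", "gene_biotype", "transcript_biotype", "transcript_type",
      "gene_type"),
    colnames(mc)
  )
  keep_bio <- rep(TRUE, sum(is_tx))
  for (bc in bio_cols) {
    b <- tolower(as.character(mc[[bc]][is_tx]))
    keep_bio <- keep_bio & (is.na(b) | b %in% .coding_biotypes)
  }

  txi <- which(is_tx)[keep_bio]
  tx_id <- as.character(mc$ID[txi])
  if (any(is.na(tx_id))) .stopf("transcript feature without ID attribute")

  # scaffold bounds from ##sequence-region pragmas, when declared
  sl <- .gff3_seqlens(path)
  seqn <- as.character(GenomicRanges::seqnames(gr))[txi]
  tx_start <- GenomicRanges::start(gr)[txi] - 1L
  tx_end <- GenomicRanges::end(gr)[txi]
  declared <- sl[seqn]
  if (any(!is.na(declared) & tx_end > declared)) {
    .stopf("transcript feature outside declared scaffold bounds")
  }

  parent <- mc$Parent
  parent1 <- vapply(as.list(parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  pick_children <- function(child_type) {
    idx <- which(type == child_type & parent1 %in% tx_id)
    split(idx, factor(parent1[idx], levels = tx_id))
  }
  exon_by_tx <- pick_children("exon")
  cds_by_tx <- pick_children("CDS")

  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  exons <- lapply(seq_along(tx_id), function(i) {
    idx <- exon_by_tx[[i]]
    if (length(idx) == 0) return(NULL)
    ex <- cbind(start = starts[idx] - 1L, end = ends[idx])
    ex[order(ex[, 1]), , drop = FALSE]
  })
  cds_start <- cds_end <- rep(NA_integer_, length(tx_id))
  for (i in seq_along(tx_id)) {
    idx <- cds_by_tx[[i]]
    if (length(idx)) {
      cds_start[i] <- min(starts[idx]) - 1L
      cds_end[i] <- max(ends[idx])
    }
  }

  .new_gene_models(
    gene_id = tx_id, scaffold_id = seqn,
    strand = as.character(GenomicRanges::strand(gr))[txi],
    tx_start = tx_start, tx_end = tx_end,
    cds_start = cds_start, cds_end = cds_end, exons = exons
  )
}

.read_bed12_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(.empty_gene_models())
  mc <- S4Vectors::mcols(gr)
  tx_start <- GenomicRanges::start(gr) - 1L
  tx_end <- GenomicRanges::end(gr)
  nm <- if (!is.null(mc$name)) as.character(mc$name) else
    paste0("tx", seq_along(gr))
  cds_start <- cds_end <- rep(NA_integer_, length(gr))
  if (!is.null(mc$thick)) {
    ts <- GenomicRanges::start(mc$thick) - 1L
    te <- GenomicRanges::end(mc$thick)
    nonzero <- !is.na(ts) & te > ts
    cds_start[nonzero] <- ts[nonzero]
    cds_end[nonzero] <- te[nonzero]
  }
  exons <- vector("list", length(gr))
  if (!is.null(mc$blocks)) {
    for (i in seq_along(gr)) {
      blk <- mc$blocks[[i]]
      if (length(blk) == 0) next
      # blocks are 1-based ranges relative to the feature start
      ex <- cbind(start = tx_start[i] + GenomicRanges::start(blk) - 1L,
                  end = tx_start[i] + GenomicRanges::end(blk))
      exons[[i]] <- ex[order(ex[, 1]), , drop = FALSE]
    }
  }
  .new_gene_models(
    gene_id = nm,
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = tx_start, tx_end = tx_end,
    cds_start = cds_start, cds_end = cds_end, exons = exons
  )
}

#' Derive transcription start sites from gene models
#'
#' The TSS is `tx_start` for `+` strand genes and `tx_end - 1` for `-` strand
#' genes (0-based coordinate of the first transcribed base). Records sharing
#' `(scaffold, position, strand)` are collapsed into one TSS with
#' `n_collapsed` recording how many gene models it represents; collapsing is
#' strand-aware because all downstream analyses are strand-directional.
#'
#' @param genes gene-model data.frame
#' @return data.frame with columns `scaffold_id`, `position`, `strand`,
#'   `n_collapsed`, sorted by scaffold then position
#' @export
derive_tss <- function(genes) {
  pos <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  key <- paste(genes$scaffold_id, pos, genes$strand, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    scaffold_id = vapply(parts, `[`, "", 1L),
    position = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    n_collapsed = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$scaffold_id, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED6
#'
#' @param x data.frame with columns `scaffold_id`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed6 <- function(x, path) {
  n <- nrow(x)
  bed <- data.frame(
    chrom = x$scaffold_id,
    start = x$start,
    end = x$end,
    name = if (!is.null(x$name)) x$name else rep(".", n),
    score = if (!is.null(x$score)) x$score else rep(0L, n),
    strand = if (!is.null(x$strand)) x$strand else rep(".", n)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as BED12
#'
#' Genes without exon structure are written as a single block; genes without a
#' CDS get a zero-width thick region at `tx_start` (the BED convention for
#' non-coding records).
#'
#' @param genes gene-model data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- genes$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) {
      ex <- cbind(start = g$tx_start, end = g$tx_end)
    }
    ts <- if (is.na(g$cds_start)) g$tx_start else g$cds_start
    te <- if (is.na(g$cds_end)) g$tx_start else g$cds_end
    paste(
      g$scaffold_id, g$tx_start, g$tx_end, g$gene_id, 0L, g$strand,
      ts, te, "0,0,0", nrow(ex),
      paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
      paste0(paste(ex[, 1] - g$tx_start, collapse = ","), ","),
      sep = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `CDS` and (where the 5' UTR is annotated)
#' `five_prime_UTR` features with `ID`/`Parent` links, converting internal
#' 0-based half-open coordinates to GFF3's 1-based closed convention.
#' Output is deterministic (fixed attribute order), so identical inputs give
#' byte-identical files.
#'
#' @param genes gene-model data.frame
#' @param path output path
#' @param seqlens optional named integer vector of scaffold lengths, written
#'   as `##sequence-region` pragmas
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path, seqlens = NULL) {
  out <- c("##gff-version 3")
  if (!is.null(seqlens)) {
    out <- c(out, sprintf("##sequence-region %s 1 %d", names(seqlens),
                          as.integer(seqlens)))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    s1 <- g$tx_start + 1L
    out <- c(out,
      sprintf("%s\tpromarch\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
              g$scaffold_id, s1, g$tx_end, g$strand, gid),
      sprintf("%s\tpromarch\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s;biotype=protein_coding",
              g$scaffold_id, s1, g$tx_end, g$strand, gid, gid))
    ex <- genes$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) {
      ex <- cbind(start = g$tx_start, end = g$tx_end)
    }
    out <- c(out, sprintf("%s\tpromarch\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                          g$scaffold_id, ex[, 1] + 1L, ex[, 2], g$strand, gid))
    if (!is.na(g$cds_start)) {
      cds <- .intersect_intervals(ex, g$cds_start, g$cds_end)
      out <- c(out, sprintf("%s\tpromarch\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                            g$scaffold_id, cds[, 1] + 1L, cds[, 2], g$strand,
                            gid))
      utr <- if (g$strand == "+") {
        .intersect_intervals(ex, g$tx_start, g$cds_start)
      } else {
        .intersect_intervals(ex, g$cds_end, g$tx_end)
      }
      if (nrow(utr)) {
        out <- c(out,
                 sprintf("%s\tpromarch\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$scaffold_id, utr[, 1] + 1L, utr[, 2], g$strand, gid))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

# clip a sorted exon matrix to [lo, hi); drops empty pieces
.intersect_intervals <- function(ex, lo, hi) {
  s <- pmax(ex[, 1], lo)
  e <- pmin(ex[, 2], hi)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}
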