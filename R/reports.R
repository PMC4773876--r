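#' Default run configuration
#'
#' Collates every stage's tunable parameters with the analysis defaults:
#' 50 kb density windows, -150/+50 core promoters, the 1 kb bidirectional
#' TSS-distance threshold, the -400..+100 positional-profile window with
#' 10 bp bins, and the 500 bp U1-PAS span.
#'
#' @param ... overrides for individual entries
#' @return named list of parameters
#' @export
run_config <- function(...) {
  cfg <- list(
    window_size = 50000L,
    min_scaffold_len = 50000L,
    mito_pattern = "MT|mito|chrM",
    upstream = 150L,
    downstream = 50L,
    promoter_min_scaffold = 10000L,
    near_threshold = 1000L,
    profile_window = c(-400L, 100L),
    bin_size = 10L,
    u1pas_span = 500L,
    score_threshold = 0.8,
    seed = 1L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

.write_report <- function(df, path, params) {
  hdr <- sprintf("# %s", paste(names(params), unlist(lapply(params, paste,
                                                            collapse = ",")),
                               sep = "=", collapse = "; "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full promoter-architecture pipeline
#'
#' Executes density -> promoters -> orientation -> scan -> co-occurrence ->
#' U1-PAS over a genome + annotation and writes one TSV per stage into
#' `out_dir`. Every emitted table carries a header line naming the parameter
#' values used. Deterministic under a fixed config.
#'
#' @param fasta path to the genome FASTA
#' @param annotation path to the gene annotation (GFF3)
#' @param out_dir output directory (created if needed)
#' @param motifs named list of `motif_model`s to profile; defaults to the
#'   canonical GC-box, its reverse complement, and the TATA consensus
#' @param config parameter list from [run_config()]
#' @param stages subset of
#'   `c("density", "promoters", "orient", "scan", "cooccur", "u1pas")`
#' @return invisible list of per-stage results
#' @export
run_pipeline <- function(fasta, annotation, out_dir, motifs = NULL,
                         config = run_config(),
                         stages = c("density", "promoters", "orient", "scan",
                                    "cooccur", "u1pas")) {
  if (!file.exists(fasta)) .stopf("missing input: %s", fasta)
  if (!file.exists(annotation)) .stopf("missing input: %s", annotation)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(motifs)) {
    motifs <- list(Sp1_GCbox = gcbox_motif(), Sp1rc = gcbox_rc_motif(),
                   TATA = tata_motif())
  }
  message("reading genome: ", fasta)
  genome <- filter_mitochondrial(read_genome(fasta), config$mito_pattern)
  message("reading annotation: ", annotation)
  genes <- read_gene_models(annotation, "gff3")
  tss <- derive_tss(genes)
  out <- list()

  if ("density" %in% stages) {
    message("stage density: window_size=", config$window_size)
    windows <- count_tss(
      tile_windows(genome, config$window_size, config$min_scaffold_len), tss)
    summary <- density_summary(genome, genes, windows, config$mito_pattern)
    .write_report(summary, file.path(out_dir, "density.tsv"),
                  config[c("window_size", "min_scaffold_len", "mito_pattern")])
    write_bed6(data.frame(scaffold_id = windows$scaffold_id,
                          start = windows$start, end = windows$end,
                          name = windows$tss_count),
               file.path(out_dir, "windows.bed"))
    out$density <- summary
    out$windows <- windows
  }

  promoters <- NULL
  if (any(c("promoters", "orient", "scan", "cooccur", "u1pas") %in% stages)) {
    message("stage promoters: upstream=", config$upstream,
            " downstream=", config$downstream)
    promoters <- filter_promoters(
      extract_core_promoters(genes, genome, config$upstream,
                             config$downstream),
      genome, config$promoter_min_scaffold)
    out$promoters <- promoters
  }
  if ("promoters" %in% stages) {
    retained <- promoters[promoters$status == "retained", , drop = FALSE]
    .write_report(promoters[, setdiff(names(promoters), "sequence")],
                  file.path(out_dir, "promoters.tsv"),
                  config[c("upstream", "downstream",
                           "promoter_min_scaffold")])
    write_bed6(data.frame(scaffold_id = retained$scaffold_id,
                          start = retained$start, end = retained$end,
                          name = retained$gene_id, strand = retained$strand),
               file.path(out_dir, "promoters.bed"))
    write_fasta(stats::setNames(retained$sequence, retained$gene_id),
                file.path(out_dir, "promoters.fa"))
  }

  if ("orient" %in% stages) {
    message("stage orient: near_threshold=", config$near_threshold)
    pairs <- adjacent_pairs(genes)
    tab <- orientation_table(pairs, config$near_threshold)
    calls <- classify_directionality(promoters, genes, config$near_threshold)
    .write_report(tab, file.path(out_dir, "orientation.tsv"),
                  config["near_threshold"])
    .write_report(calls, file.path(out_dir, "directionality.tsv"),
                  config["near_threshold"])
    out$orientation <- tab
    out$directionality <- calls
  }

  hit_sets <- NULL
  if (any(c("scan", "cooccur", "u1pas") %in% stages)) {
    message("stage scan: window=[", config$profile_window[1], ",",
            config$profile_window[2], ") bin=", config$bin_size)
    retained <- promoters[promoters$status == "retained", , drop = FALSE]
    anchors <- data.frame(scaffold_id = retained$scaffold_id,
                          position = retained$tss_position,
                          strand = retained$strand,
                          gene_id = retained$gene_id,
                          stringsAsFactors = FALSE)
    profiles <- lapply(motifs, function(m)
      positional_profile(anchors, genome, m, config$profile_window,
                         config$bin_size))
    out$profiles <- profiles
    if ("scan" %in% stages) {
      prof_df <- do.call(rbind, lapply(names(profiles), function(nm) {
        p <- profiles[[nm]]
        data.frame(motif = nm, bin_start = p$bin_start,
                   bin_end = p$bin_start + p$bin_size,
                   frequency = p$frequency, n_regions = p$n_regions,
                   stringsAsFactors = FALSE)
      }))
      .write_report(prof_df, file.path(out_dir, "profiles.tsv"),
                    config[c("profile_window", "bin_size",
                             "score_threshold")])
    }
    hit_sets <- lapply(profiles, function(p)
      unique(anchors$gene_id[p$hits$anchor]))
  }

  if ("cooccur" %in% stages && length(hit_sets) >= 2) {
    message("stage cooccur")
    n_tested <- sum(promoters$status == "retained")
    co <- cooccurrence_table(hit_sets, n_tested)
    .write_report(co, file.path(out_dir, "cooccur.tsv"), list(n = n_tested))
    out$cooccurrence <- co
  }

  if ("u1pas" %in% stages) {
    message("stage u1pas: span=", config$u1pas_span)
    bg <- .base_counts(genome)[c("A", "C", "G", "T")]
    u1pas_motifs <- list(PAS = pas_motif(),
                         SS5 = donor_motif(background = unname(bg / sum(bg))))
    rows <- list()
    for (nm in names(u1pas_motifs)) {
      for (d in c("sense_downstream", "antisense_upstream")) {
        cp <- cumulative_motif_frequency(tss, genome, u1pas_motifs[[nm]], d,
                                         config$u1pas_span, config$bin_size)
        rows[[paste(nm, d)]] <- data.frame(
          motif = nm, direction = d,
          distance_bin = config$bin_size * seq_along(cp$cumulative),
          per_bin_frequency = cp$per_bin_frequency,
          cumulative = cp$cumulative, stringsAsFactors = FALSE)
      }
    }
    u1pas <- do.call(rbind, rows)
    .write_report(u1pas, file.path(out_dir, "u1pas.tsv"),
                  config[c("u1pas_span", "bin_size")])
    out$u1pas <- u1pas
  }

  invisible(out)
}
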