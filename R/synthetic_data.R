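#' Configuration for the synthetic genome simulator
#'
#' Defaults describe the study conditions the pipeline is validated under: a
#' multi-scaffold genome of roughly 2.6 Mb with the 64.2% AT composition of a
#' compact AT-rich sponge genome, 2,000 protein-coding genes laid out as
#' 1,000 configured adjacent pairs with a 25/25/50 head-to-head /
#' tail-to-tail / head-to-tail orientation mixture, head-to-head TSS
#' distances of 320-1,000 bp (within the 1 kb bidirectional window but far
#' enough apart that the two 200 bp core promoters never overlap), and
#' compact gene structure (about one intron of ~100 bp per gene, ~120 bp
#' exons, 250-600 bp intergenic gaps) so the gene count fits the genome
#' size. Samplers are functions of `n` drawing from the configured
#' distributions.
#'
#' @param n_scaffolds number of scaffolds
#' @param scaffold_length_bp length of each scaffold
#' @param at_fraction genome AT fraction (A and T equiprobable)
#' @param n_genes total genes to place (must be even: genes are placed as
#'   configured pairs)
#' @param orientation_mix probabilities `(head_to_head, tail_to_tail,
#'   head_to_tail)` for the configured pairs, summing to 1
#' @param tss_distance_sampler sampler for head-to-head TSS-to-TSS distances
#' @param intergenic_sampler sampler for non-head-to-head intra-pair gaps
#' @param pair_separation_bp spacer between consecutive configured pairs
#'   (> 1 kb so only intra-pair structure is "near")
#' @param intron_count_sampler,intron_size_sampler,exon_size_sampler gene
#'   structure samplers
#' @param utr5_len_bp annotated 5' UTR length (bp)
#' @param p_annotated_utr5 fraction of genes given an annotated 5' UTR (the
#'   rest have the CDS starting at the TSS, so no annotated promoter)
#' @param motif_plants list of `list(consensus=, offset_mean=, offset_sd=,
#'   fraction=)` descriptors for [plant_motifs()]
#' @param pas_rates,ss5_rates named numeric
#'   `(sense_downstream_per_kb, antisense_upstream_per_kb)` planting rates
#'   for [plant_directionality_signals()]
#' @return a `simulation_config` list
#' @export
simulation_config <- function(
    n_scaffolds = 4L,
    scaffold_length_bp = 660000L,
    at_fraction = 0.642,
    n_genes = 2000L,
    orientation_mix = c(head_to_head = 0.25, tail_to_tail = 0.25,
                        head_to_tail = 0.5),
    tss_distance_sampler = function(n) sample(320:1000, n, replace = TRUE),
    intergenic_sampler = function(n) sample(250:600, n, replace = TRUE),
    pair_separation_bp = 1200L,
    intron_count_sampler = function(n) stats::rpois(n, 1),
    intron_size_sampler = function(n) pmax(60L, round(stats::rexp(n, 1 / 120))),
    exon_size_sampler = function(n) sample(100:140, n, replace = TRUE),
    utr5_len_bp = 60L,
    p_annotated_utr5 = 1.0,
    motif_plants = list(),
    pas_rates = c(sense_downstream_per_kb = 0, antisense_upstream_per_kb = 0),
    ss5_rates = c(sense_downstream_per_kb = 0, antisense_upstream_per_kb = 0)) {
  stopifnot(
    n_scaffolds >= 1, scaffold_length_bp > 0,
    at_fraction >= 0, at_fraction <= 1,
    n_genes %% 2 == 0,
    length(orientation_mix) == 3, all(orientation_mix >= 0),
    abs(sum(orientation_mix) - 1) < 1e-8,
    p_annotated_utr5 >= 0, p_annotated_utr5 <= 1,
    all(pas_rates >= 0), all(ss5_rates >= 0)
  )
  structure(as.list(environment()), class = "simulation_config")
}

.random_dna <- function(n, at_fraction) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at_fraction / 2, at_fraction / 2,
                        (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
        collapse = "")
}

# one gene's internal structure; returns total length and exon offsets
.gene_structure <- function(config) {
  k <- config$intron_count_sampler(1)
  ex <- config$exon_size_sampler(k + 1)
  intr <- if (k > 0) config$intron_size_sampler(k) else integer(0)
  # exon offsets within the gene (0-based half-open)
  starts <- cumsum(c(0, if (k > 0) ex[-(k + 1)] + intr else integer(0)))
  list(length = sum(ex) + sum(intr),
       exons = cbind(start = starts, end = starts + ex))
}

#' Simulate a genome with configured gene pairs
#'
#' Background sequence is i.i.d. with the configured AT fraction. Genes are
#' placed left to right as configured pairs: within a pair the orientation
#' category is drawn from `orientation_mix` (head-to-head pairs get a TSS
#' distance from `tss_distance_sampler`; other pairs an intergenic gap from
#' `intergenic_sampler`), and consecutive pairs are separated by
#' `pair_separation_bp` so intra-pair structure is the only "near"
#' configuration. Placement moves to the next scaffold when the current one
#' is full; if all scaffolds fill before `n_genes` are placed, the packing is
#' infeasible and an error is raised. Deterministic under a fixed seed.
#'
#' @param config a [simulation_config()]
#' @param seed integer RNG seed
#' @return list with `genome` (named character vector), `genes` (gene-model
#'   data.frame), and `truth` (list with `pairs`: configured pair table with
#'   planted `category` and `tss_distance_bp`)
#' @export
simulate_genome <- function(config, seed = 1L) {
  set.seed(seed)
  genome <- stats::setNames(
    vapply(seq_len(config$n_scaffolds), function(i)
      .random_dna(config$scaffold_length_bp, config$at_fraction),
      character(1)),
    sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  )

  n_pairs <- config$n_genes %/% 2L
  margin <- 1000L  # keeps promoter/flank windows on-scaffold
  L <- config$scaffold_length_bp
  cats <- c("head_to_head", "tail_to_tail", "head_to_tail")

  genes <- list()
  pairs <- list()
  gi <- 0L
  sc <- 1L
  cursor <- margin
  for (p in seq_len(n_pairs)) {
    category <- sample(cats, 1, prob = config$orientation_mix)
    g1 <- .gene_structure(config)
    g2 <- .gene_structure(config)
    strands <- switch(category,
      head_to_head = c("-", "+"),
      tail_to_tail = c("+", "-"),
      head_to_tail = rep(sample(c("+", "-"), 1), 2)
    )
    tssd <- NA_integer_
    if (category == "head_to_head") {
      tssd <- as.integer(config$tss_distance_sampler(1))
      left_start <- cursor
      right_start <- left_start + g1$length - 1L + tssd
    } else {
      gap <- as.integer(config$intergenic_sampler(1))
      left_start <- cursor
      right_start <- left_start + g1$length + gap
    }
    pair_end <- right_start + g2$length
    if (pair_end + margin > L) {
      sc <- sc + 1L
      if (sc > config$n_scaffolds) {
        .stopf("infeasible packing: %d genes placed, %d requested",
               gi, config$n_genes)
      }
      cursor <- margin
      left_start <- cursor
      if (category == "head_to_head") {
        right_start <- left_start + g1$length - 1L + tssd
      } else {
        right_start <- left_start + g1$length +
          as.integer(config$intergenic_sampler(1))
      }
      pair_end <- right_start + g2$length
      if (pair_end + margin > L) {
        .stopf("infeasible packing: scaffold shorter than one pair")
      }
    }
    scid <- names(genome)[sc]
    for (side in 1:2) {
      gi <- gi + 1L
      gs <- if (side == 1) g1 else g2
      start <- if (side == 1) left_start else right_start
      genes[[gi]] <- .place_gene(
        id = sprintf("g%05d", gi), scaffold_id = scid, strand = strands[side],
        tx_start = start, structure = gs, config = config
      )
    }
    pairs[[p]] <- data.frame(
      scaffold_id = scid,
      left_gene_id = sprintf("g%05d", gi - 1L),
      right_gene_id = sprintf("g%05d", gi),
      category = category,
      tss_distance_bp = tssd,
      stringsAsFactors = FALSE
    )
    cursor <- pair_end + config$pair_separation_bp
  }

  genes <- do.call(rbind, genes)
  validate_gene_models(genes)
  list(genome = genome, genes = genes,
       truth = list(pairs = do.call(rbind, pairs), config = config,
                    seed = seed))
}

.place_gene <- function(id, scaffold_id, strand, tx_start, structure,
                        config) {
  ex <- structure$exons
  ex <- cbind(start = tx_start + ex[, "start"], end = tx_start + ex[, "end"])
  tx_end <- tx_start + structure$length
  annotated <- stats::runif(1) < config$p_annotated_utr5
  # the UTRs live in the transcript's terminal exons (strand-dependent side)
  ex5 <- if (strand == "+") ex[1, ] else ex[nrow(ex), ]
  ex3 <- if (strand == "+") ex[nrow(ex), ] else ex[1, ]
  u5 <- min(config$utr5_len_bp, ex5[2] - ex5[1] - 10L)
  u3 <- min(30L, ex3[2] - ex3[1] - 10L)
  if (strand == "+") {
    cds_start <- if (annotated) tx_start + u5 else tx_start
    cds_end <- tx_end - u3
  } else {
    cds_start <- tx_start + u3
    cds_end <- if (annotated) tx_end - u5 else tx_end
  }
  df <- data.frame(
    gene_id = id, scaffold_id = scaffold_id, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    stringsAsFactors = FALSE
  )
  df$exons <- list(ex)
  df$has_annotated_5utr <- .has_utr5(df)
  df
}

.sample_iupac_instance <- function(consensus) {
  cls <- strsplit(chartr("Uu", "TT", toupper(consensus)), "", fixed = TRUE)[[1]]
  paste(vapply(cls, function(k) {
    choices <- .IUPAC[[k]]
    choices[sample.int(length(choices), 1)]
  }, character(1)), collapse = "")
}

#' Plant motif instances into promoter windows
#'
#' For each plant descriptor, a random subset of the promoters (binomial with
#' the configured `fraction`) has background bases overwritten by a sampled
#' instance of the consensus (IUPAC classes sampled uniformly within class)
#' at a sense-relative offset drawn from `round(rnorm(offset_mean,
#' offset_sd))`, clipped so the site fits inside the promoter window. Planted
#' sites never overlap one another (collisions are redrawn a bounded number
#' of times). Every insertion is recorded in the returned truth table.
#'
#' @param genome named character vector of scaffold sequences
#' @param promoters retained promoter data.frame from
#'   [extract_core_promoters()] / [filter_promoters()]
#' @param motif_plants list of `list(consensus=, offset_mean=, offset_sd=,
#'   fraction=)`
#' @param seed integer RNG seed
#' @return list `genome` (modified), `truth` (data.frame `gene_id`,
#'   `scaffold_id`, `strand`, `offset`, `genomic_start`, `consensus`,
#'   `instance`)
#' @export
plant_motifs <- function(genome, promoters, motif_plants, seed = 1L) {
  set.seed(seed)
  gl <- .explode_genome(genome)
  pr <- promoters[promoters$status == "retained", , drop = FALSE]
  truth <- list()
  used <- list()  # per scaffold: planted genomic intervals
  ti <- 0L
  for (plant in motif_plants) {
    w <- nchar(plant$consensus)
    chosen <- which(stats::runif(nrow(pr)) < plant$fraction)
    for (i in chosen) {
      up <- pr$tss_position[i] -
        (if (pr$strand[i] == "+") pr$start[i] else pr$end[i] - 1L)
      up <- abs(up)
      down <- (pr$end[i] - pr$start[i]) - up
      lo <- -up
      hi <- down - w
      if (hi < lo) .stopf("planted motif wider than the promoter window")
      placed <- FALSE
      for (try in 1:20) {
        off <- as.integer(round(stats::rnorm(1, plant$offset_mean,
                                             plant$offset_sd)))
        off <- max(lo, min(hi, off))
        gstart <- if (pr$strand[i] == "+") {
          pr$tss_position[i] + off
        } else {
          pr$tss_position[i] - off - w + 1L
        }
        sc <- pr$scaffold_id[i]
        iv <- used[[sc]]
        if (!is.null(iv) && any(gstart < iv[, 2] & gstart + w > iv[, 1])) next
        inst <- .sample_iupac_instance(plant$consensus)
        gl <- .write_site_v(gl, sc, gstart,
                            if (pr$strand[i] == "+") inst else revcomp(inst))
        used[[sc]] <- rbind(iv, c(gstart, gstart + w))
        ti <- ti + 1L
        truth[[ti]] <- data.frame(
          gene_id = pr$gene_id[i], scaffold_id = sc,
          strand = pr$strand[i],
          offset = if (pr$strand[i] == "+") off else
            as.integer(pr$tss_position[i] - (gstart + w - 1L)),
          genomic_start = as.integer(gstart),
          consensus = plant$consensus, instance = inst,
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) .stopf("could not place motif without overlap (gene %s)",
                          pr$gene_id[i])
    }
  }
  truth <- if (ti > 0) do.call(rbind, truth) else
    data.frame(gene_id = character(), scaffold_id = character(),
               strand = character(), offset = integer(),
               genomic_start = integer(), consensus = character(),
               instance = character(), stringsAsFactors = FALSE)
  list(genome = .collapse_genome(gl), truth = truth)
}

# exploded genome representation (per-scaffold character vectors) so site
# writes do not copy whole scaffold strings
.explode_genome <- function(genome) {
  lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
}
.collapse_genome <- function(gl) {
  vapply(gl, paste, character(1), collapse = "")
}
.write_site_v <- function(gl, sc, start, what) {
  gl[[sc]][(start + 1L):(start + nchar(what))] <-
    strsplit(what, "", fixed = TRUE)[[1]]
  gl
}

# Every anchor reads one flank rightward (genomic [p+1, p+span]) and one
# leftward ([p-span, p-1], extracted as the reverse complement); which of the
# two is "sense downstream" depends on the anchor's strand. Chance matches of
# `motif` inside any reading-right flank (forward matches) or reading-left
# flank (reverse-complement matches) are rewritten from the genome's base
# composition until none remain, so planted rates are the rates the
# cumulative profiles measure.
.neutralize_flanks <- function(gl, anchors, motif, span) {
  comp_v <- table(factor(unlist(gl, use.names = FALSE),
                         levels = c("A", "C", "G", "T")))
  comp <- as.numeric(comp_v) / sum(comp_v)
  bases <- c("A", "C", "G", "T")
  w <- motif$width
  for (sc in unique(anchors$scaffold_id)) {
    pos <- anchors$position[anchors$scaffold_id == sc]
    for (sweep in 1:10) {
      seqs <- paste(gl[[sc]], collapse = "")
      h <- if (motif$kind == "pwm") scan_pwm(seqs, motif, "both")
           else scan_iupac(seqs, motif, "both")
      if (nrow(h) == 0) break
      # a forward site [s, s+w) is read by right flanks of anchors at
      # p in [s - span, s + w - 2]; a reverse-complement site by left flanks
      # of anchors at p in [s + 1, s + w - 1 + span]
      in_flank <- vapply(seq_len(nrow(h)), function(k) {
        s <- h$start[k]
        if (h$strand[k] == "sense") {
          any(pos >= s - span & pos <= s + w - 2L)
        } else {
          any(pos >= s + 1L & pos <= s + w - 1L + span)
        }
      }, logical(1))
      if (!any(in_flank)) break
      for (s in h$start[in_flank]) {
        gl <- .write_site_v(gl, sc,
                            s, paste(sample(bases, w, replace = TRUE,
                                            prob = comp), collapse = ""))
      }
    }
  }
  gl
}

# genomic 0-based start of the leftmost base of a site whose 5'-most read
# base sits at `distance` (1-based) from the anchor in the given direction
.flank_to_genomic <- function(position, strand, direction, distance, w) {
  reading_right <- (strand == "+") == (direction == "sense_downstream")
  if (reading_right) position + distance
  else position - distance - w + 1L
}

#' Plant strand-asymmetric PAS / 5' splice-site signals around anchors
#'
#' Emulates the differential accumulation of polyadenylation signals and
#' splice-donor sites around promoters: for every anchor and each
#' direction (sense-downstream on the coding strand, antisense-upstream on
#' the template strand), a Poisson number of sites with mean
#' `rate_per_kb * span / 1000` is written into the flank at uniform random
#' distances, on the strand the direction reads. Pre-existing chance matches
#' of the planted motifs in those flanks are first neutralised (rewritten
#' from the background composition) so the planted rates are the rates the
#' profiles measure. Planted sites never overlap; every site is recorded in
#' the truth table.
#'
#' @param genome named character vector of scaffold sequences
#' @param tss_records anchor data.frame (`scaffold_id`, `position`, `strand`)
#' @param pas_rates,ss5_rates numeric
#'   `(sense_downstream_per_kb, antisense_upstream_per_kb)`
#' @param seed integer RNG seed
#' @param span flank length in bp
#' @param neutralize rewrite chance matches in the flanks before planting
#' @return list `genome` (modified), `truth` (data.frame `scaffold_id`,
#'   `position`, `strand`, `signal`, `direction`, `distance`,
#'   `genomic_start`, `instance`)
#' @export
plant_directionality_signals <- function(genome, tss_records, pas_rates,
                                         ss5_rates, seed = 1L, span = 500L,
                                         neutralize = TRUE) {
  set.seed(seed)
  pas <- pas_motif()
  donor <- donor_motif()
  donor_site <- "CAGGTAAGT"  # consensus of the synthetic donor PFM
  signals <- list(
    list(name = "PAS", motif = pas, rates = pas_rates,
         instance = function() .sample_iupac_instance("AWTAAA")),
    list(name = "SS5", motif = donor, rates = ss5_rates,
         instance = function() donor_site)
  )
  gl <- .explode_genome(genome)
  if (neutralize) {
    for (sig in signals) {
      if (any(sig$rates > 0)) {
        gl <- .neutralize_flanks(gl, tss_records, sig$motif, span)
      }
    }
  }

  # anchor positions per scaffold, to keep each planted site visible to
  # exactly one flank: a site planted reading right for the anchor at p must
  # not fall inside the right-reading flank [q+1, q+span] of any other
  # anchor q (and symmetrically for left-reading sites), otherwise it would
  # be double-counted by a neighbouring profile
  pos_by_sc <- split(tss_records$position, tss_records$scaffold_id)

  truth <- list()
  ti <- 0L
  used <- list()
  dirs <- c(sense_downstream = 1L, antisense_upstream = 2L)
  for (i in seq_len(nrow(tss_records))) {
    sc <- tss_records$scaffold_id[i]
    p_i <- tss_records$position[i]
    others <- pos_by_sc[[sc]]
    others <- others[others != p_i]
    sc_len <- length(gl[[sc]])
    for (d in names(dirs)) {
      for (sig in signals) {
        rate <- sig$rates[[dirs[[d]]]]
        if (rate <= 0) next
        w <- sig$motif$width
        n_sites <- stats::rpois(1, rate * span / 1000)
        if (n_sites == 0) next
        reading_right <- (tss_records$strand[i] == "+") ==
          (d == "sense_downstream")
        placed <- 0L
        for (try in seq_len(50L * n_sites)) {
          if (placed >= n_sites) break
          dist <- sample.int(span - w, 1)
          gstart <- .flank_to_genomic(p_i, tss_records$strand[i], d, dist, w)
          if (gstart < 0 || gstart + w > sc_len) next
          if (reading_right) {
            if (any(others >= gstart - span & others <= gstart + w - 2L)) next
          } else {
            if (any(others >= gstart + 1L &
                    others <= gstart + w - 1L + span)) next
          }
          iv <- used[[sc]]
          if (!is.null(iv) && any(gstart < iv[, 2] & gstart + w > iv[, 1])) {
            next
          }
          inst <- sig$instance()
          gl <- .write_site_v(gl, sc, gstart,
                              if (reading_right) inst else revcomp(inst))
          used[[sc]] <- rbind(iv, c(gstart, gstart + w))
          ti <- ti + 1L
          truth[[ti]] <- data.frame(
            scaffold_id = sc, position = p_i,
            strand = tss_records$strand[i], signal = sig$name,
            direction = d, distance = as.integer(dist),
            genomic_start = as.integer(gstart), instance = inst,
            stringsAsFactors = FALSE
          )
          placed <- placed + 1L
        }
        if (placed < n_sites) {
          .stopf("planting rate too high: could not place %d %s sites",
                 n_sites, sig$name)
        }
      }
    }
  }
  genome <- .collapse_genome(gl)
  truth <- if (ti > 0) do.call(rbind, truth) else
    data.frame(scaffold_id = character(), position = integer(),
               strand = character(), signal = character(),
               direction = character(), distance = integer(),
               genomic_start = integer(), instance = character(),
               stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}
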