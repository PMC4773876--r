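---
title: "Promoter architecture in compact genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter architecture in compact genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(promarch)
```

## The analysis

`promarch` quantifies the regulatory architecture around transcription start
sites (TSSs) in gene-dense genomes. The pipeline has six stages, each a thin
layer over one statistical idea:

1. **Gene density.** Scaffolds of at least 50 kb are tiled into
   non-overlapping 50 kb windows (a trailing remainder is dropped so every
   window measures exactly "genes per 50 kb") and unique TSSs are counted
   per window. A *gene desert* is a window with no TSS. The summary reports
   genes/Mb (gene count over non-mitochondrial megabases), the median
   per-window count, the desert percentage over tiled windows, %AT over
   non-N bases, and intron statistics.
2. **Core promoters.** The TSS is the start of the annotated 5′ UTR; a gene
   whose CDS begins at the TSS has no annotated promoter and is set aside.
   The core promoter is the window 150 bp upstream to 50 bp downstream of
   the TSS, reported 5′→3′ on the gene's sense strand with the TSS at
   sequence offset 150. Windows are discarded with a fixed precedence:
   off-scaffold, overlapping an assembly gap (any N), on a scaffold not
   strictly longer than 10 kb, on a scaffold carrying a CpG island of 10 kb
   or more (a bacterial-contamination signature in AT-rich assemblies), and
   finally any base shared with another promoter (both members of an
   overlapping pair are dropped, so the retained set is mutually
   non-overlapping).
3. **Orientation and directionality.** Consecutive genes per scaffold
   (ordered by start, ties by end) form pair regions: head-to-head when the
   left gene is on − and the right on + (divergent 5′ ends), tail-to-tail
   for the converse, head-to-tail otherwise. A head-to-head pair whose TSSs
   are ≤1 kb apart (TSS-to-TSS, inclusive; overlapping pairs are eligible)
   marks a bidirectional promoter region: both promoters retained → both
   *bidirectional*; exactly one retained → *putative bidirectional*; all
   other retained promoters are *unidirectional*. The three classes
   partition the retained set by construction.
4. **Motif scanning and positional enrichment.** A motif is a position
   frequency matrix (PFM) or an IUPAC consensus. PFMs become log-odds PWMs:
   score(b, j) = log2(((count + pseudocount·bg_b) / (N_j + pseudocount)) /
   bg_b), with a per-column pseudocount of 0.25 split by the background. A
   window is a hit when its summed score reaches a configurable fraction
   (default 0.8) of the motif's maximum achievable score; all overlapping
   and tied hits are reported, and windows containing N never match (IUPAC
   classes exclude N; PWM windows with N score −∞). Positional profiles bin
   hits by the offset of the site's 5′-most sense-strand base relative to
   the TSS, in 10 bp bins across −400..+100 (the TSS sits at offset 0 in
   bin [0,10)); the frequency is hits per bin over the number of anchors
   with complete, gap-free windows.
5. **Co-occurrence.** Enrichment is promoter-level presence/absence: with
   n_a and n_b promoters carrying each motif out of n, the expected overlap
   under independence is n_a·n_b/n, the ratio is observed/expected, and
   significance is the exact hypergeometric upper tail (a seeded permutation
   mode cross-checks the same null). Overlapping hit instances still count.
6. **The U1-PAS axis.** For each anchor, the 500 bp flank starting at
   offset +1 downstream on the coding strand, and the 500 bp flank starting
   at −1 upstream read on the template strand away from the anchor, are
   scanned for same-strand matches of the polyadenylation-signal consensus
   (AWUAAA; DNA `AWTAAA`) or a splice-donor PWM. Hits are binned by the
   distance of their 5′-most base (bin b covers distances 10b+1..10(b+1)),
   and the cumulative profile is the running sum of per-bin frequencies. The
   anchor base itself (offset 0) belongs to neither flank. All hits count,
   so the profile mass equals total hits per anchor; cumulative vectors are
   non-decreasing by construction and this is asserted on every run.
   Profiles can be re-anchored on motif occurrences (e.g. GC-box hits near
   TSSs) instead of TSSs.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| window size | 50,000 bp | gene-density window |
| promoter window | −150..+50 bp | core promoter around the TSS |
| near threshold | 1,000 bp | TSS distance for bidirectionality (inclusive) |
| profile window | −400..+100 bp | positional-enrichment span, 10 bp bins |
| U1-PAS span | 500 bp | directional flank length, 10 bp bins |
| PWM threshold | 0.8 × max score | hit cutoff, per motif |
| CpG island | GC ≥ 0.5, obs/exp ≥ 0.6, 200 bp windows, ≥10 kb | contamination gate |
| min scaffold | >10 kb | promoter host scaffolds |

The CpG-island criteria are the classic sliding-window definition
(GC fraction and observed/expected CpG = #CG·L/(#C·#G) per 200 bp window,
qualifying windows merged); only the ≥10 kb length gate is specific to the
contamination use. All thresholds are arguments.

Design choices that were genuinely open, and how they were fixed:

- **TSS deduplication is strand-aware** (a shared position on opposite
  strands stays two TSSs) because every downstream analysis is
  strand-directional.
- **"Within 1 kb" is TSS-to-TSS and inclusive**, and overlapping
  head-to-head pairs remain eligible for bidirectional classification
  (their TSS distance is still defined).
- **Both members of an overlapping promoter pair are dropped**; the
  exclusion is symmetric.
- **The scaffold-longer-than-10-kb filter is strict** (>10,000 bp), and the
  CpG-contamination filter acts per scaffold (the contamination rationale is
  an assembly-level one).
- **Soft-masked bases are uppercased and kept**; ambiguity codes become N,
  and N never matches any scanner.
- **All hits are counted in profiles** (not at most one per bin per
  anchor), keeping profile mass conservation exact with the scanners.
- The published per-window desert percentages for real genomes are not
  targeted: their exact denominator is not recoverable from the printed
  counts, so the package reports its own stated definition
  (desert windows / tiled windows).

## What the simulator emulates

`simulation_config()` describes the study conditions under which the
pipeline is validated. Background sequence is i.i.d. mononucleotide with
64.2% AT — the composition of the compact sponge genome this analysis style
was developed for. Genes are placed as 1,000 *configured pairs* (2,000
genes, ~2.6 Mb over four scaffolds) with a 25/25/50
head-to-head/tail-to-tail/head-to-tail mixture; head-to-head pairs draw
TSS-to-TSS distances from 320–1,000 bp — inside the 1 kb bidirectional
window but far enough apart that two 200 bp core promoters never overlap —
and consecutive pairs are separated by 1.2 kb so intra-pair geometry is the
only "near" structure. Gene structure is deliberately compact (Poisson(1)
introns of ~120 bp, 100–140 bp exons, 250–600 bp intergenic gaps): with
realistic sponge-scale intron load (~4 introns of ~330 bp and ~590 bp
intergenic distances) 2,000 genes would need roughly twice the sequence,
and the validation targets per-promoter statistics, not genome-length
realism.

Orientation mixtures are planted on disjoint configured pairs rather than
on a single chain of adjacent genes: consecutive adjacent pairs share a
gene, so independent category draws over one chain are mathematically
infeasible (a head-to-head adjacency forces the shared gene's strand).
Recovery properties therefore evaluate the configured pairs recorded in the
truth table.

`plant_motifs()` overwrites promoter bases with sampled instances of a
consensus at configured offsets; `plant_directionality_signals()` plants a
Poisson number of PAS/5′SS sites per directional flank at configured per-kb
rates. Two details make the planted rates exactly the rates the profiles
measure. First, chance background matches in the anchored flanks are
neutralised before planting (rewritten from the background composition
until none remain) — in a 64.2% AT genome the chance AWTAAA rate is about
one hit per 500 bp flank, which would otherwise swamp planted rates of
0.5–1.5 sites per flank. Second, a site is never placed where a
*different* anchor's same-reading flank would also count it (gene-dense
layouts make flanks overlap), at the cost of a slightly non-uniform
position distribution inside shared regions. Sites never overlap one
another; every insertion is recorded in the truth table.

What the simulator does **not** emulate — dinucleotide structure,
repeats/transposons, isoforms sharing TSSs, soft-masking, chained (rather
than paired) orientation dependence, and evolutionary signal — bounds what
passing tests show: they validate the measurement machinery (coordinates,
strand handling, binning, counting, test calibration) against known truth,
not the biological claims one would make from a real genome.

## Numerical and statistical choices

- Internal coordinates are 0-based half-open everywhere; GFF3 is converted
  on read (1-based closed), BED is native. The − strand TSS is
  `tx_end − 1`.
- Report percentages round half-up to one decimal (so 20.95% prints as
  21.0%), matching how genome summary tables are conventionally printed.
- The hypergeometric p-value is the conservative upper tail
  P(X ≥ observed). Being discrete, its null distribution is super-uniform
  with atoms, so the calibration test applies the randomized
  probability-integral transform P(X > x) + U·P(X = x) — the standard
  uniformity check for discrete exact tests — while the reported p-value
  stays the raw tail.
- The expected-overlap model is the marginal product n_a·n_b/n; the seeded
  permutation mode provides the empirical cross-check of the same null.
- Degenerate inputs: empty window lists and zero promoters tested are
  errors; a gene set with no introns reports mean intron size 0 with a
  warning; an expected co-occurrence of 0 with a positive observed count
  reports an infinite ratio; anchors with truncated flanks are dropped and
  counted.
- Ties in gene ordering (identical starts, e.g. nested genes) break by
  transcript end; overlapping or tied PWM hits are all reported, never
  greedily masked.
- The shipped splice-donor matrix is synthetic (9 columns, invariant GT at
  columns 4–5, consensus `CAGGTAAGT`) and is labelled as such; analyses of
  real data should supply a database donor matrix via the JASPAR/MEME
  readers.

## Problem sizes

Validation runs use the full study configuration: 2,000 promoters on the
~2.6 Mb simulated genome for positional recovery and the U1-PAS ratio,
100 random sequences × 5 motifs for scanner–oracle equivalence, and 1,000
simulated promoter sets of 500 promoters for the co-occurrence null. These
sizes put binomial sampling error well inside the acceptance bands (e.g.
±1.1 percentage points at n = 2,000 for a 50% planted share).

## Known limitations

- The GFF3 reader expects `mRNA`/`transcript` features with `exon`/`CDS`
  children linked by `Parent` and a biotype attribute for non-coding
  filtering; exotic attribute dialects may need pre-processing.
- CpG-island detection with step 1 is O(scaffold length) per scaffold in
  memory; for chromosome-scale scaffolds a larger step is advisable.
- Directionality classification uses annotation-derived head-to-head
  structure as the proxy for bidirectional transcription; expression-based
  evidence (RNA-seq coverage of divergent transcripts) is out of scope.
- The per-window desert percentages of published tables for real genomes
  are intentionally not reproduced (unstated denominator; see above).
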