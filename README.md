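# promarch

Promoter-architecture analysis for compact genomes.

Gene-dense genomes — sponges, choanoflagellates, tunicates — pack genes so
tightly that a large fraction of adjacent gene pairs sit head-to-head with
transcription start sites (TSSs) less than a kilobase apart, sharing what is
effectively one bidirectional promoter. `promarch` implements the analyses
used to characterise such promoter landscapes from a genome FASTA and a GFF3
annotation:

- **Gene density**: unique TSSs per non-overlapping 50 kb window, summarised
  as genes/Mb, median genes per window, and gene-desert fraction.
- **Core promoters**: the −150..+50 window around each annotated TSS (TSS =
  start of the annotated 5′ UTR), with exclusion filters for windows that run
  off a scaffold, overlap an assembly gap, overlap another promoter, or sit
  on short (≤10 kb) or CpG-contaminated scaffolds.
- **Orientation and directionality**: adjacent gene pairs classified
  head-to-head / tail-to-tail / head-to-tail; promoters classified
  *bidirectional* (head-to-head pair ≤1 kb apart, both promoters retained),
  *putative bidirectional* (only one retained), or *unidirectional*.
- **Motif scanning**: log-odds PWM scanning (score threshold as a fraction
  of the maximum achievable score) and IUPAC consensus matching; positional
  frequency profiles per 10 bp bin across −400..+100 around the TSS;
  nucleotide/dinucleotide composition profiles; JASPAR raw and MEME minimal
  motif readers.
- **Co-occurrence**: promoter-level presence/absence enrichment of motif
  pairs with the exact hypergeometric upper-tail test
  (observed/expected ratio with expected = n_a·n_b/n).
- **The U1-PAS axis**: cumulative frequency of polyadenylation signals
  (AWUAAA; DNA `AWTAAA`) and 5′ splice sites, per 10 bp bin over 500 bp
  downstream of the TSS on the coding strand and 500 bp upstream on the
  template strand — the statistic that exposes the strand asymmetry thought
  to confer promoter directionality.
- **Synthetic genomes**: a simulator that emits FASTA + GFF3 with configured
  AT content, gene-pair orientation mixture, TSS spacing and gene structure,
  plus functions that plant motifs at known offsets and PAS/5′SS sites at
  known strand-asymmetric rates — so every stage can be validated against
  planted truth.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a thin
driver over the package and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # synthetic study genome
Rscript analysis/02_gene_density.R        # 50 kb windowing + density summary
Rscript analysis/03_promoters_orientation.R
Rscript analysis/04_motif_profiles.R      # positional profiles + co-occurrence
Rscript analysis/05_u1_pas.R              # cumulative PAS / 5'SS asymmetry
```

A run prints, among other things:

```
simulated 4 scaffolds (2.64 Mb), 2000 genes, 1000 configured pairs
Sp1_GCbox: argmax bin start -30, 50.4% of promoters carry a hit
planted GC-box share 50.0%; recovered 50.4%
co-occurrence: observed 335 vs expected 338.7 (ratio 0.99, p = 0.654)
PAS final cumulative: sense 0.539, antisense 1.541 (ratio 2.86; planted 3.0)
SS5 final cumulative: sense 1.000, antisense 0.496 (ratio 2.01; planted 2.0)
```

Reading: a GC-box planted at offset −30 in 50% of the 2,000 promoters is
recovered in the right 10 bp bin and at the planted promoter share; two
motifs planted independently show a co-occurrence ratio of ~1 (no
enrichment); and polyadenylation signals planted three times as densely on
the upstream-antisense side are recovered as a cumulative-frequency ratio of
~3, the signature the U1-PAS axis analysis is designed to detect.

The same code paths reproduce the published summary numbers when fed the
printed counts (e.g. 40,122 genes / 166.7 Mb → 240.7 genes/Mb; the
orientation-table percentages 22.3 / 21.0 / 56.8 from its overlapping and
non-overlapping counts; 45% head-to-head genes; 26% TATA-containing
promoters).

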