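# itrtools

Genome-scale analysis of *Hsmar1* inverted terminal repeats (ITRs) and
SETMAR/Metnase chromatin binding.

SETMAR is a human fusion protein whose mariner-transposase domain still
binds the 19-nt ITR core motif 5'-GGTGCAAAAGTAATTGCGG-3' left behind by
thousands of decayed *Hsmar1* transposons, *MADE1* miniature elements
(MITEs) and solo ITRs. Because those relics have drifted neutrally, their
copies carry 0-3 substitutions relative to the core: stratifying loci by
Hamming distance to the motif ("mismatch groups" 0MM-3MM) and overlaying
ChIP coverage asks, genome-wide, how motif **fidelity** determines binding
**affinity** — and how binding relates to the expression of associated
genes.

`itrtools` implements the full pipeline:

* **`scan_motif()`** — degenerate scanning of a FASTA genome on both
  strands with up to *k* mismatches (Hamming distance; windows containing
  N are skipped; overlapping matches resolved deterministically), plus
  `group_by_mismatch()`, `mismatch_profile()` ("17:C>T"-style profiles).
* **`pair_itrs()`** — classification into MITE-like elements (two ITRs
  with inner gap ≤ 500 bp) and solo ITRs; `element_length_summary()`,
  `solo_itrs_by_group()`.
* **`overlap_peaks_itrs()`, `annotate_summits()`, `randomize_peaks()`,
  `enrichment_test()`, `peak_enrichment()`, `chromosome_correlation()`**
  — ChIP-peak/ITR overlap, HOMER-style summit categories
  (TSS > TTS > exon > intron > intergenic), and enrichment against
  blacklist-aware randomized interval nulls using the pooled
  two-proportion z test (z² equals the 2×2 χ² without continuity
  correction).
* **`scores_by_group()`, `rank_sum_test()`, `substitution_effects()`** —
  mean ChIP signal per ITR by mismatch group (with a random genomic
  background group), Wilcoxon rank-sum with an exact enumeration branch
  for small samples, and per-substitution affinity effects over 1MM solo
  ITRs (frequency < 2% classes excluded; fold change as ratio of
  medians).
* **`associate_genes()`, `expression_compare()`** — gene association over
  TSS-exon-intron-TTS spans, grouping by minimum mismatch, and FPKM
  comparison against a seeded random gene group.
* **`simulation_config()`, `generate_genome()`, `generate_chip()`,
  `generate_expression()`, `simulate_study()`** — a synthetic-data
  generator with planted, scanner-verified truth so the whole pipeline
  runs and is tested offline.

Standard formats are handled through Bioconductor (Biostrings,
GenomicRanges, rtracklayer): FASTA, BED6+ hit files, narrowPeak,
bedGraph, GTF, chrom.sizes and FPKM TSV.

## Worked example

The default simulated study plants 800 ITR loci (200 MITE pairs + 400
solos, on four chromosomes plus a motif-free gene-background chromosome),
fidelity-biased ChIP peaks and signal, and fidelity-repressed expression:

```r
library(itrtools)

cfg  <- simulation_config(seed = 1)
sim  <- generate_genome(cfg)
hits <- scan_motif(sim$genome, motif_spec())
group_by_mismatch(hits)
#> 0MM 1MM 2MM 3MM
#> 189 197 223 191

el <- pair_itrs(hits)
element_length_summary(el)$median_length   # 67 bp across 200 MITEs

chip <- generate_chip(sim)
v <- overlap_peaks_itrs(chip$peaks, hits)
#> 318/323 peaks overlap an ITR (98.5%); 402/800 ITRs lie in peaks (50.2%)

scores_by_group(chip$track, hits, background_n = 2000, seed = 2,
                blacklist = sim$blacklist)$summary
#>   group    n   median
#> 1   0MM  189 100.0239
#> 2   1MM  197  11.6461
#> 3   2MM  223   0.9067
#> 4   3MM  191   0.2841
#> 5 Total 2000   0.0408

peak_enrichment(chip$peaks, list(ITR = hits), blacklist = sim$blacklist,
                n_sets = 50, seed = 3)
#>   category observed expected ratio    z  p.value
#> 1      ITR      318      211  1.51 12.5 1.23e-35

expr  <- generate_expression(sim)
assoc <- associate_genes(hits, expr$genes)
expression_compare(assoc, expr$fpkm, seed = 4)$tests
#>    group   n median p_vs_random
#> 1    MM0  39   2.46    9.01e-09
#> 2    MM1  46   2.35    3.25e-06
#> 3    MM2  43   4.42    4.20e-03
#> 4    MM3  22  10.99    4.79e-02
#> 5 random 150   8.13          NA
```

Reading the output: the scan recovers every planted locus (plus any
accidental background match, which the generator verifies and records);
mean ChIP score per ITR falls monotonically with mismatch count while
random background sits near zero; peaks are strongly enriched on ITRs
versus the randomized null; and genes whose best ITR is high-fidelity
(MM0) show the strongest expression repression relative to a random gene
group, fading toward MM3.

A thin command-line front end over the same functions is in
`inst/scripts/itr-pipeline.R` (subcommands `scan`, `classify`, `enrich`,
`affinity`, `expression`, `simulate`). A full-scale hg38 reproduction
script — requiring a locally downloaded assembly FASTA — is in
`inst/scripts/reproduce-hg38.R`.

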