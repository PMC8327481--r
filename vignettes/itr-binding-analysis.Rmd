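---
title: "Mapping ITR fidelity and SETMAR binding: methods and design notes"
author: "itrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ITR fidelity and SETMAR binding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itrtools)
```

## The problem

The human SETMAR (Metnase) protein is a domesticated fusion of a SET
histone-methyltransferase domain with the *Hsmar1* mariner transposase.
The transposase moiety retains sequence-specific DNA binding to the
*Hsmar1* inverted terminal repeat (ITR), whose 19-nt core is
5'-GGTGCAAAAGTAATTGCGG-3'. Thousands of decayed *Hsmar1* relics persist in
the human genome: full and internally deleted transposons flanked by two
ITRs, *MADE1*-type miniature inverted-repeat transposable elements (MITEs,
two ITRs with little internal sequence), and solo ITRs. Because these
relics have been drifting neutrally for tens of millions of years, their
ITR copies carry varying numbers of substitutions relative to the core
motif. That natural mutational spectrum turns the genome into a saturation
mutagenesis experiment: by stratifying ITR loci by their Hamming distance
to the core motif (mismatch groups 0MM-3MM) and overlaying ChIP coverage
of tagged SETMAR, one can ask how motif *fidelity* maps onto binding
*affinity*, and how binding maps onto the expression of nearby genes.

`itrtools` implements that analysis as a reusable, fully testable
pipeline:

1. **genome scanning** — degenerate matching of the ITR core on both
   strands with up to `max_mismatch` mismatches (`scan_motif()`);
2. **element annotation** — classification of hits into MITE-like pairs
   and solo ITRs (`pair_itrs()`);
3. **peak analysis** — overlap of ChIP peaks with ITRs and genomic
   features, with enrichment tested against blacklist-aware randomized
   interval nulls (`overlap_peaks_itrs()`, `annotate_summits()`,
   `randomize_peaks()`, `enrichment_test()`, `peak_enrichment()`,
   `chromosome_correlation()`);
4. **affinity analysis** — mean ChIP signal per ITR stratified by
   mismatch group, and per-substitution effects over 1MM solo ITRs
   (`scores_by_group()`, `rank_sum_test()`, `substitution_effects()`);
5. **expression analysis** — association of genes with ITRs over
   TSS-exon-intron-TTS spans and comparison of FPKM distributions by best
   ITR fidelity against a random gene group (`associate_genes()`,
   `expression_compare()`);
6. **simulation** — a synthetic-data generator with a hit-level truth
   table so every stage runs and is verified offline
   (`simulation_config()`, `generate_genome()`, `generate_chip()`,
   `generate_expression()`, `simulate_study()`).

## Scanning model

A window is a hit when its Hamming distance to the motif (or, on the minus
strand, the distance of its reverse complement) is at most `max_mismatch`
(default 3, i.e. up to ~16% divergence over 19 nt). Three choices deserve
comment:

* **Ambiguous bases.** Any window containing a base outside A/C/G/T is
  never a hit: an N cannot be counted as identical or as a mismatch
  without inventing information, so the conservative call is to skip it.
  Soft-masked (lowercase) sequence is uppercased and scanned normally —
  repeat masking would remove precisely the transposon relics under
  study.
* **Overlap resolution.** Degenerate matching can produce overlapping
  candidate windows. Each locus should carry a single annotation, so
  overlapping candidates are resolved greedily: lowest mismatch count
  wins, ties prefer the plus strand, then the leftmost start; survivors
  are accepted only if they do not overlap an already-accepted hit. The
  rule is deterministic and order-independent. For the ITR core this
  matters only for shifted overlaps: the motif and its reverse complement
  differ at 15 of 19 positions, so no window can match both strands
  within 3 mismatches (the plus-strand tie-break is still implemented and
  exercised with an artificial palindromic motif in the tests).
* **Coordinates.** Internally hits are `GRanges` (1-based, closed), the
  native Bioconductor convention, so every downstream overlap operation
  composes with the standard tool set; BED/bedGraph/narrowPeak files are
  written and read 0-based half-open as those formats require. Mismatch
  positions are reported 1-based in motif coordinates ("17:C>T" for the
  C17-to-T change), matching the field's base-plus-position naming.

The scanner itself is a vectorized shifted-comparison: for a motif of
width w it performs w vector comparisons per strand per chromosome, so a
megabase scans in about a second. A deliberately naive all-windows oracle
(explicit per-window character comparison, per-window reverse
complementation, quadratic overlap resolution) ships in the test suite and
the scanner is required to agree with it exactly on random and
planted-motif genomes.

## Element classification

Two hits on the same chromosome whose inner gap (downstream start minus
upstream end, exclusive) is at most `max_gap` = 500 bp form a MITE-like
element; everything else is a solo ITR. The gap measures the *internal*
sequence of the candidate element, consistent with miniature elements
whose median total length is near 68 bp. Pairing is greedy left-to-right —
each unpaired hit pairs with its nearest eligible downstream neighbour —
which is deterministic and order-independent for a fixed hit set; in
chains of three or more nearby hits the leftmost pair wins and the
remainder becomes solo. Pairing does **not** require inverted (+/−)
orientation by default, because the defining published criterion is
distance alone; `require_inverted = TRUE` restricts pairing to +/−
orientation for sensitivity analyses. Increasing `max_gap` can never
decrease the MITE count (a property the tests check).

## Peak analysis

Peaks are consumed, not called: narrowPeak (with summit offsets) or BED6
input. For overlap statistics peaks are extended ±500 bp and overlap means
at least one shared base, half-open arithmetic on disk and closed-interval
arithmetic in `GRanges` giving identical answers. Summit annotation uses a
fixed priority TSS > TTS > exon > intron > intergenic with strand-aware
windows TSS = [tss−1000, tss+100] and TTS = [tts−100, tts+1000] bp
(configurable); the priority makes the categorization total and
deterministic regardless of gene input order.

The null model is randomized peak sets that preserve the per-chromosome
peak count and the exact multiset of peak lengths, placed uniformly over
the complement of the blacklist by a cumulative allowed-gap table (no
rejection sampling, so even an almost-fully-blacklisted chromosome is
handled exactly; a peak longer than the largest allowed gap is an error
naming the peak). Random peaks may overlap each other, like standard
interval shufflers. Every run asserts zero blacklist overlap. How many
randomized sets the original analysis used is not stated anywhere we
could find, so `n_sets` is explicit (default 100) and the expected count
is the mean per set while the z-test pools all sets.

Enrichment per category uses the pooled two-proportion z statistic; its
square equals the 2×2 chi-square without continuity correction, which the
tests assert, and swapping the arguments negates z. Raw two-sided
p-values are reported with no multiple-testing correction — the upstream
analysis style this mirrors reports raw p at α = 0.05, and the categories
are few and pre-registered; users comparing many feature sets should
apply `p.adjust` themselves.

## Affinity analysis

"Affinity" is operationalized as the length-weighted mean of the per-base
ChIP coverage over the 19-bp hit itself (not the extended peak): the
quantity is an average score per ITR, and widening the window would dilute
locus-specific signal with flanking background. Uncovered bases count as
zero. The genomic background group ("Total") is `background_n` (default
10,000) random motif-length windows placed outside the hits and the
blacklist with the same rejection-free sampler, under a caller-supplied
seed.

`rank_sum_test()` is the two-sample Wilcoxon rank-sum: for combined sizes
up to 12 the two-sided p-value comes from full enumeration of all rank
assignments (a permutation test on the rank-sum statistic, valid under
ties via average ranks — the {1,2,3} vs {4,5,6} case gives exactly
p = 0.1); larger samples delegate to the normal approximation with tie
and continuity correction. The two branches agree within |Δp| ≤ 0.05 at
the boundary, which the tests check against independent references.

The single-substitution analysis takes 1MM **solo** ITRs (solo, so that a
partner ITR cannot recruit binding to the locus), groups them by
(position, from-base, to-base), and drops groups whose frequency among
1MM solos is strictly below 2% — rare substitution classes have too few
loci for a stable median. Pre-filter frequencies always sum to 100%. Each
retained group is compared against 0MM solos by rank-sum, and the fold
change is the ratio of medians (0MM median / group median): medians
because coverage distributions are heavy-tailed and a handful of open
chromatin loci would otherwise dominate a mean-based ratio.

## Expression analysis

A gene is associated with the binding landscape when at least one ITR hit
falls inside the union of its TSS window, exons, introns and TTS window;
association by peak summits is available as a mode for analyses that
trust peak calls more than motif matches (`mode = "summits"`). The gene's
fidelity group is the *minimum* mismatch among its ITRs — the
highest-fidelity site is the strongest candidate binding site, and the
assignment is invariant to hit ordering. Genes with several expression
records keep their maximum FPKM. The comparison group is a seeded random
draw from non-associated genes, sized to the associated total by default,
from either all genes or only expressed ones (`universe`), since how the
original random gene group was drawn is not stated; both modes are
provided and the default is "all".

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
standard simulated study:

| parameter | default | rationale |
|---|---|---|
| chromosomes | 4, 360/320/280/240 kb | multi-chromosome genome small enough to scan in seconds; lengths vary so per-chromosome ITR counts covary with length |
| fixed-group loci | 20/30/25/25 for 0-3MM | a known per-group census for exact recovery tests |
| MITE pairs | 200, inner gap U(20, 40) bp | element lengths 58-78 bp, median ≈ 68 bp, the canonical MITE size |
| extra solos | 300, uniform groups | bulk of loci are solos, as in real genomes |
| element spacing | U(1250, 1600) bp | beyond both the 500-bp pairing window and the 1000-bp TSS window, so planted truth is unambiguous |
| blacklist | ~5% of the genome | realistic excluded fraction; placed ≥300 bp from planted loci |
| substitution spectrum (1MM) | C17>T 18%, C17>A 15%, G18>A 20%, G18>T 18%, G2>A 2%, G4>A 2%, remainder spread thin | mirrors the reported predominance of clock-like C-to-T/G-to-A changes and the published per-position frequencies; the thin remainder falls below the 2% filter, exercising it |
| peak fractions | 0.8/0.5/0.2/0.1 for 0-3MM | peaks preferentially on high-fidelity ITRs |
| signal | S0 = 100, decay 0.5 per mismatch, σ = 5, ±150 bp plateaus | signal proportional to fidelity with realistic noise; position multipliers (strongest at motif position 17) reproduce the substitution-effect structure |
| expression | log-normal, log-mean shifts −1/−0.5/−0.25/0 for MM0-MM3 | repression scales with fidelity |

Background sequence is uniform-random A/C/G/T, so accidental matches
within 3 mismatches are possible though rare (the expected count per
simulated genome is well below one); the generator re-scans its own
output, verifies that every planted locus is recovered with its designed
mismatch count, and appends any accidental background matches to the
truth table labelled `origin = "background"` — truth is what is verifiably
in the sequence, not what was intended. Non-associated background genes
live on a dedicated motif-free chromosome so the random gene group is
clean by construction. One master seed drives everything; per-artifact
child seeds are derived from it deterministically so the genome, the ChIP
layer and the expression layer can be regenerated independently.
`generate_loci()` exposes the positional layer without sequence for
statistical simulations (power and null calibration) where only locus
geometry matters.

What the generator deliberately does **not** emulate: nucleotide
composition bias and repeat structure of real genomes, read-level noise
and mappability artifacts, chromatin-state-dependent binding (in real data
only a fraction of high-fidelity ITRs is bound at any time), correlated
peaks, and dosage/isoform structure in expression. Passing tests
therefore demonstrate that the *computational* pipeline recovers known
truth and that its tests are calibrated — not that the biological effect
sizes in real data match the simulation's.

## Numerical and testing choices

* Exact enumeration in `rank_sum_test()` switches to the normal
  approximation above a combined n of 12 (924 subsets at the boundary —
  enumeration stays instantaneous, and beyond it the approximation is
  accurate).
* The frequency filter in `substitution_effects()` applies *strictly
  below* the cutoff: a group at exactly 2% is retained.
* `enrichment_test()` returns z = 0, p = 1 for identical proportions,
  including the degenerate pooled-proportion-0 or -1 cases.
* Null calibration in the tests draws "observed" peaks with the same
  uniform placement used for the randomized sets (the fidelity-driven
  peak fraction set to zero), then checks that enrichment and expression
  p-values are uniform over 200 seeds by Kolmogorov–Smirnov at the 1%
  level.
* Test problem sizes: scanner-oracle equivalence on twenty 50-kb random
  genomes; planted-truth recovery on the full default study (~1.5 Mb);
  fidelity-affinity monotonicity on 100 replicates of 400 loci
  (100/group); null calibration on 200 seeds with 200 peaks and 10
  randomized sets per seed. These sizes give stable statistics while the
  whole suite runs in minutes on one CPU.

## Limitations

* Indel or gapped matching and PWM scoring are out of scope; divergence
  is modelled as substitutions only.
* The pipeline consumes aligned, normalized inputs (peaks, bedGraph,
  FPKM); alignment, deduplication, peak calling and normalization are
  upstream concerns.
* Absolute affinity values depend on the upstream coverage normalization
  (bin size, smoothing); only relative and ordinal statements across
  groups are meaningful.
* Classification of full-length versus internally deleted transposon
  bodies requires a transposase consensus and is not attempted; elements
  are classified from ITR geometry alone.
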