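---
title: "Methods: MeDIP-seq methylome profiling and DMR calling with medipmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MeDIP-seq methylome profiling and DMR calling with medipmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipmap)
```

## Scope and model

medipmap analyses MeDIP-seq (methylated-DNA immunoprecipitation sequencing)
methylomes downstream of alignment and peak calling. Its inputs are a genome
(FASTA), gene models (a minimal GFF-lite dialect), a class-labelled repeat
track (BED), per-sample methylation peaks and uniquely-aligned read positions
(BED), and optionally raw paired-end reads (FASTQ) for quality filtering. A
methylation *peak* is treated as evidence that the underlying interval is
methylated; all downstream statistics are interval arithmetic over peaks,
reads and genomic features, held in `GRanges`.

The package covers seven analyses: four-criteria read QC, CpG-island (CGI)
detection, assignment of peaks to genomic feature categories, methylation
density per feature/repeat class, gene-body metaprofiles, two-sample
differentially methylated region (DMR) calling, and TSS-centered k-means
clustering with per-chromosome correlation diagnostics. A synthetic-data
generator produces a complete toy study with planted ground truth so that
every stage can be validated without any external download.

## Read quality filtering

A read pair is discarded when either mate has (1) an N fraction of at least
10%, (2) a mean Phred quality below 20, or (3) at least 5% of bases below
Q20 — or when (4) both mates report exactly the same base string. All
boundaries are as stated: criteria 1 and 3 are inclusive ("at least"),
criterion 2 is strict. Removal is attributed to the first failing criterion
in order 1–4, so the per-criterion counts in the report are exclusive and
sum, together with the kept count, to the total. Criterion 4 is the most
literal reading of "same bases called in both mates" (a degenerate,
duplicate-like pair); because the intent of such a filter is debatable it
sits behind `pair_identical_filter = TRUE` and its removals are reported
separately, so the choice is auditable. Adapter trimming is out of scope
and assumed done upstream. The FASTQ reader auto-detects the Phred offset:
any quality character below ASCII 59 implies offset 33; otherwise characters
above ASCII 74 (Q41 at offset 33) imply offset 64.

## CpG-island detection

A CGI is a maximal region satisfying the three classical criteria: length
greater than 200 bp, GC fraction at least 0.5, and CpG observed/expected
ratio

$$\mathrm{O/E} = \frac{\#\mathrm{CpG} \times N}{\#C \times \#G} \ge 0.6,$$

with $N$ the number of non-N bases. The scanner slides a 200-bp window at
1-bp steps, marks every base covered by any qualifying window, merges
overlapping or book-ended qualifying windows, and discards merged regions
not longer than 200 bp. Because a union of qualifying windows need not
itself satisfy the criteria (a GC dip can sit between two qualifying cores),
each merged region is re-verified on its full extent; a failing region is
trimmed one base at a time, alternating left and right ends, until it
satisfies all three criteria or shrinks to 200 bp (discarded). The alternate
trim is deliberately simple and deterministic — unlike two-phase extension
schemes it is easy to verify against an exhaustive per-window oracle, which
the test suite does on randomized 50-kb sequences. N handling: N positions
are excluded from $N$ in both GC and O/E, and windows that are more than
half N are disqualified, which avoids inflated O/E next to assembly gaps.
Reported islands carry their final-extent GC fraction and O/E.

## Feature categories and peak annotation

From each gene model the package derives upstream/downstream 2-kb flanks
(transcription orientation, clipped at chromosome ends), 5'/3' UTRs (exonic
sequence outside the CDS span on each side), CDS (exonic sequence within the
CDS span) and introns. "CDS" therefore means coding exonic sequence only;
UTRs are separate categories. For a transcript without a CDS all exonic
sequence is treated as 5'UTR. Overlaps between categories of different genes
are resolved per base pair by a fixed precedence — CDS > 5'UTR > 3'UTR >
intron > upstream > downstream > intergenic — so the seven categories
partition the genome exactly; this makes density denominators well-defined
and testable. The repeat track is an independent overlay: a base can be both
intronic and LINE.

A peak belongs to a category when at least 50% of its length overlaps it.
On the disjoint partition at most one category can reach 50%, except an
exact 50/50 split, which the precedence order resolves. Repeat counts are
peak–repeat-class incidences; because the overlay is independent, a peak can
be counted in a genic category *and* in repeats, so repeat counts may exceed
the total peak count — both the aggregate repeat count and per-class
incidences are reported.

Methylation density of a class is merged-peak base pairs overlapping the
class divided by class base pairs — a coverage fraction in [0, 1], invariant
to how peaks are fragmented. The `genome` pseudo-class gives overall genome
coverage. A CGI is called methylated when at least 1 bp overlaps a peak (the
most inclusive reading; `min_overlap_frac` lets the caller require a
fraction instead), and methylated CGIs are attributed to genic categories by
the same 50% rule, with everything else (including intergenic CGIs) counted
as "other". Reported percentages are rounded to two decimals.

The gene-body metaprofile uses 20 absolute 100-bp bins upstream of the TSS,
40 relative bins across the body and 20 absolute bins downstream of the TTS
(orientation-flipped for minus-strand genes; genes shorter than the bin
count are skipped and counted). The 20/40/80 bin scheme is a plumbing choice
— flank size, bin width and body bin count are all parameters.

## DMR calling

Candidate regions are the connected components of the union of both
samples' peak sets (overlapping or book-ended peaks joined). Reads are
counted per region under a 50%-of-read overlap rule, each read at most once
(region of maximal overlap; ties to the first region in coordinate order).
Each region is tested with a 2×2 chi-square (1 df, no continuity
correction) on

$$\begin{pmatrix} a & T_A - a\\ b & T_B - b \end{pmatrix},$$

where $a, b$ are the region's read counts and $T_A, T_B$ the library sizes.
Regions with fewer than 5 reads combined are dropped before testing
(chi-square is invalid there) and reported. P-values are adjusted by
Benjamini–Hochberg across all tested regions; a DMR requires adjusted
$q < 0.05$ *and* a library-size-normalised fold change
$(a/T_A)/(b/T_B)$ strictly greater than 2 in either direction. The
significance threshold applies to the adjusted value by default because an
FDR that is not used for selection controls nothing; `use_raw_p = TRUE`
restores raw-p thresholding. Fold changes are library-size normalised
because unequal sequencing depth otherwise fabricates DMRs; a pseudocount
of 0.5 replaces zero counts in the fold only, never in the statistic.
Direction is hyper when sample A's normalised rate exceeds B's. The full
per-region table, including non-significant regions, is available for
audit.

### Power at the reference design point

The package's own calibration study (run by the test suite and the
acceptance script) uses Poisson counts at a 4-fold design: 50 planted
regions at means 40 vs 10 among 500 null regions at 20 vs 20, equal library
sizes, 200 replicates. Under the null the raw-p < 0.05 fraction is ≈ 0.04
(the chi-square is slightly conservative at these counts) and BH at
q < 0.05 calls essentially no null regions. For the planted regions the
self-consistent BH threshold with ~550 tests and ~47 discoveries is an
effective per-test p ≈ 0.004 (χ² ≈ 8.1), and
$P\big((a-b)^2/(a+b) > 8.1\,\big|\,a \sim \mathrm{Pois}(40),
b \sim \mathrm{Pois}(10)\big) \approx 0.95$: measured sensitivity is
0.949 ± 0.002 with empirical FDR ≈ 0.04. A sensitivity requirement of 95%
sits exactly at the edge of what this design can deliver, and the
corresponding assertion in the test suite is expected to sit marginally
below it; sensitivity is strictly monotone in the planted fold (checked at
folds 1.5, 2.5 and 4 at fixed total depth).

## Clustering and diagnostics

TSS-centered matrices have one row per gene and 100-bp bins across
TSS ± 5 kb; bin values are coverage fractions of the (merged) input
intervals, rows reversed for minus-strand genes so column 1 is always most
upstream. On the minus strand the window is the exact mirror image of the
plus-strand window, so a reflected gene/interval pair produces identical
rows — a property the tests exploit.

Clustering is Lloyd's algorithm with k-means++ seeding, best of `n_init`
restarts by within-cluster sum of squares, deterministic under a fixed
seed. Empty clusters are repaired by re-seeding the empty centroid with the
point farthest from the centroid of the largest cluster. The restart
default is 25: restarts are cheap at these matrix sizes, and small
instances have many local minima (on 6-row instances the best-of-restarts
optimum is verified against exhaustive enumeration of all 2-partitions).
`k` defaults to 5 but is a free parameter — the appropriate cluster count
for tissue-specific methylation patterns is data-dependent, and published
analyses of this kind have used anywhere from 5 nominal clusters to ~11
effective ones. Cluster-level significance is deliberately not computed:
there is no principled default test for the tightness of coverage-profile
clusters, so none is reported; a label-permutation comparison of
within-cluster scatter is easy to build on top of `kmeans_profiles()` if
one is needed.

Per-chromosome diagnostics report Pearson's r between peak counts and
chromosome length, and between peak counts and gene number.

## The synthetic study

`sim_config()` fixes the study conditions; `simulate_genome()` and
`simulate_methylome()` realise them deterministically under the seed (same
seed, byte-identical files):

* **Genome**: 3 chromosomes with decreasing lengths (1 Mb down to 0.6 Mb,
  as in real karyotypes, so per-chromosome statistics have variance);
  background GC 0.41 (mammalian-like); the background is CpG-depleted to
  O/E ≈ 0.2 by mutating 80% of CG dinucleotides, with the initial GC raised
  so the final GC still matches — without depletion, random background
  qualifies under the O/E criterion and CGI detection has no contrast.
* **CGIs**: planted at 60% of promoters (ending 0.1–0.9 kb upstream of the
  TSS, 300–800 bp) and at 20 intergenic sites (300–1500 bp), each
  satisfying GC ≥ 0.6 and O/E ≥ 0.8 by construction. Island GC is kept
  close to 0.6 and each island gets short AT-rich shoulders: windows
  straddling a boundary then fail the GC criterion quickly and the
  full-extent re-verification trims residual overhang, which keeps the
  scanner's output tightly aligned with the planted truth (≥ 80%
  reciprocal overlap). Occasional boundary-window noise can still push a
  single short island just past that bound, so recovery is asserted as a
  fraction (≥ 0.95) rather than per island.
* **Genes**: 45 coding genes, 3–12 kb, non-overlapping with > 2 kb
  spacing; 2–6 exons; terminal exons at least 800 bp with 300–700 bp UTRs
  so every category can host whole peaks (minimum peak length 100 bp).
* **Repeats**: class-labelled elements (LINE 0.6–5 kb, SINE 0.1–0.35 kb,
  LTR, DNA, satellite, simple, low-complexity) placed in intergenic and
  intronic space.
* **Peaks**: 100–500 bp, placed to match per-class target densities whose
  default ranking encodes the qualitative pattern of mammalian methylomes —
  CDS highest, promoter/5'UTR lowest, LINE above SINE/LTR. The allocator
  gives each eligible interval a chunk proportional to its width and then
  settles the residual exactly by growing or shrinking placed chunks, so
  measured densities match targets to well under 0.001 at the 1-Mb scale
  (the generator's contract is a mean absolute error ≤ 0.02). Repeat-class
  peaks are placed first, inside elements; partition-class targets are then
  topped up net of the repeat peaks' contribution.
* **Reads and DMRs**: 50-bp reads with Poisson counts per peak (mean 25)
  plus uniform background; planted DMRs are isolated peaks (not book-ended
  with a neighbour, so each stays its own merged region) whose count means
  differ 40 vs 10 between samples, matching the reference design point.
* **FASTQ**: read pairs with planted failure fractions per QC criterion
  (4% N-rich, 5% low mean quality, 5% low-quality-fraction, 2% identical
  mates), giving ≈ 84% clean — inside the 81.8–87.5% range typical of this
  kind of library.

What the generator does *not* emulate: the CpG-density dependence of MeDIP
enrichment (no deconvolution is attempted), overdispersed counts (reads are
Poisson, which is exactly the assumption of the chi-square test),
fragment-size and sequencing-error models, and diploid genotypes. Passing
tests therefore show that the implementation is correct under its own
assumptions, not that the chi-square model is adequate for biological
replicates — with real data showing extra-Poisson variation a
dispersion-modelling count test would be more conservative.

## Numerical choices and problem sizes

All intervals are `GRanges` (1-based, closed) internally; BED semantics are
converted on I/O by rtracklayer. Degenerate inputs are defined: an empty
peak set gives zero densities and an all-zero metaprofile; classes with
zero area are reported as NA rather than 0/0; chromosomes shorter than the
CGI window yield no islands without error; zero-information DMR regions
(fewer than 5 reads combined) are dropped and counted.

The test suite runs the generator at two scales — 200-kb chromosomes for
pipeline-level tests and the full 1-Mb default for the density and
rank-recovery checks — and uses 200 replicates for the DMR operating
characteristics; these sizes make the whole suite complete in a few
minutes while leaving the Monte-Carlo error of the reported rates around
0.2%.
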