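---
title: "Footprint calling and 5'UTR feature analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint calling and 5'UTR feature analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seclipr)
```

## The problem

seCLIP maps where an RNA-binding protein contacts the transcriptome:
UV-crosslinked protein–RNA complexes are immunoprecipitated, and sequencing
reads pile up into clusters at contact sites. Because immunoprecipitation
also recovers abundant RNA nonspecifically, a cluster is only believable if
it is *enriched* over a paired INPUT library (the lysate before
immunoprecipitation) and reproducible across biological replicates; clusters
that also appear in negative-control immunoprecipitations (an IgG pull-down
with no tagged protein, and a binding-dead ΔRRM transgene that reports
indirect crosslinking) are background. seclipr implements this retention
logic as a small set of composable steps, together with the downstream
questions one asks of an initiation factor's footprints: which gene features
they occupy, how coverage distributes around start and stop codons, and
whether target 5′UTRs are longer or more GC-rich than the transcriptome.

## The retention rule

Reads are merged per replicate into maximal same-strand clusters
(`build_clusters`); clusters overlapping or book-ended across the two
replicates are unioned into a consensus window. A window becomes a footprint
(`call_footprints`) iff

1. it holds at least one read in **both** replicates, and
2. in **at least one** replicate, the read count is ≥ `min_reads` (20) and
   the RPM fold change over INPUT is ≥ `min_fc` (1.5),

with `FC = (RPM_CLIP + c)/(RPM_INPUT + c)` and pseudocount `c = 1` RPM.
Thresholds are inclusive ("at least"). The sentence defining the rule can be
read two ways — thresholds in at least one replicate, or in each — so both
are implemented (`threshold_scope`), with `either_replicate` the default
reading; presence in both replicates is required in either mode.

Three choices here were genuinely open:

* **INPUT counting.** INPUT reads are counted over the CLIP consensus window
  itself rather than over independently clustered INPUT data, so enrichment
  is always a ratio over a common window. Independently called INPUT
  clusters would make the fold change depend on how INPUT happened to
  fragment.
* **Pseudocount.** Enrichment on RPM with `c = 1` RPM tolerates zero-input
  windows (a window with 10 CLIP RPM and no INPUT reads gets FC 11, not
  infinity) while leaving FC = 1 exact whenever CLIP equals INPUT.
* **Merging semantics.** `min_gap = 0` merges overlapping *and* book-ended
  reads — the bedtools `merge -d 0` convention — so that a cluster is a
  maximal run of contiguous coverage.

Background subtraction (`subtract_background`) removes a footprint on any
≥ 1 bp same-strand overlap with a control footprint. Overlap (rather than
identity of cluster IDs) is the defensible choice when the control clusters
were called independently; a stricter reciprocal-overlap variant would keep
footprints whose edges merely graze a control cluster, which is not what a
"background region" means physically.

## Feature categories and the metagene

`annotate_footprints` assigns one label per footprint with precedence
`five_prime_proximal > three_prime_utr > intron > non_coding > intergenic`.
5′UTR and CDS overlaps share the top category because initiation-factor
clusters in the CDS sit almost exclusively within ~200 nt of the start
codon; keeping them apart would split one biological signal across two
labels. Within the winning category the gene with the largest base overlap
is assigned, ties broken by the lexicographically smaller gene id
(determinism over arbitrariness).

`metagene_coverage` accumulates each footprint's RPM over every
transcript-space base it covers inside a window around the start or stop
codon. Offsets are *spliced* distances — introns are excluded — because
that is the coordinate in which a scanning ribosome experiences the 5′UTR.
Each gene contributes through one anchored transcript, the isoform with the
longest 5′UTR (the same selection used for UTR extraction, so modules
agree). The default window (−300, +300) nt covers the (−150, +200) span
where this class of signal concentrates, with margin. A footprint's RPM is
the mean of its two replicate CLIP RPMs. Coverage is computed from footprint
intervals, not from the raw reads inside them; output therefore represents
"footprint occupancy", which is the quantity the retention rule certifies.

## 5′UTR features

`extract_five_prime_utrs` applies two filters before any statistics: UTRs
shorter than 10 nt are dropped (too short for meaningful length/GC
measurement; the threshold is inclusive, 10 nt passes) and only the longest
5′UTR isoform per gene is kept, so a gene with many annotated transcripts is
not counted repeatedly. Ties on length are broken by the smallest
transcript id. Sequences are spliced and reverse-complemented for minus-strand
genes, ending immediately before the ATG.

GC is reported as total fraction and in 10-nt bins counted *back* from the
ATG (bin 1 is adjacent to the start codon), so positional GC enrichment near
the start codon versus the distal 5′ end is visible. The final, most-5′ bin
may be partial and reports its true length; it is included, not dropped,
which makes the length-weighted mean of bin GC equal the total GC exactly —
a conservation invariant the tests enforce at 1e-12. Characters outside
ACGTU are rejected by default, naming the offending position; an N-tolerant
mode counts N as non-GC and reports the N fraction, for annotations lifted
from draft assemblies. An optional spliced-leader prefix can be stripped
before feature computation, mirroring the practice of excluding SL1 leader
sequence when analysing gene-specific 5′UTR content.

Group comparisons use the two-sided Mann-Whitney test: exact null
distribution for tie-free samples with combined n ≤ 25, otherwise the normal
approximation with tie and continuity correction (`stats::wilcox.test`
provides both regimes). Medians are midpoint-of-order-statistics; percentile
tables span 5–95, the box-plot convention for these data. The trans-splice
join counts a target as spliced only if it appears in the supplied table
(absence is evidence of absence in a curated compilation), and reports the
percentage rounded to the nearest integer — 133 of 225 prints 59.

## Polysome quantification

`simpson_auc` integrates baseline-subtracted absorbance over a named region
with composite Simpson's rule on the uniform sampling grid. Regions are
given in position units and snapped to the nearest sample point. When a
region spans an odd number of intervals, Simpson's rule covers the first
even count and the last interval is added by the trapezoid rule — standard,
bounded error, no resampling. Post-baseline negative values are clipped to
zero: absorbance below the optical baseline is instrument noise, and letting
it cancel real signal would bias areas low. The default baseline is 0
(integration of the raw trace); `estimate_baseline` offers a constant
baseline from a user-named blank region, since whether traces should be
baseline-subtracted before integration is a per-instrument decision — both
modes are exposed. `pm_ratio` is the polysome area over the monosome (80S)
area, the usual one-number summary of global translational activity.

## The synthetic-data generator

`simulate_genome` builds a single chromosome of genes with promoter gap,
5′UTR, CDS (30% of genes carry one intron, placed ≥ 45 nt into the CDS), and
3′UTR, on random strands. Its defaults are the study conditions the package
emulates: target-gene 5′UTR lengths log-normal with median 93 nt at 42% GC,
background genes median 69 nt at 39% GC (log-normal because lengths are
positive and right-skewed, matching 5–95 percentile boxes qualitatively;
sdlog 0.6), GC realised per-base Bernoulli at the gene's GC probability, and
~70% of genes annotated as trans-spliced. Each target gene carries one
planted footprint spanning the 3′-most ≤ 40 nt of its 5′UTR plus the first
20 nt of CDS.

`simulate_clip` emits (WT, C130Y, ΔRRM, IgG) × (CLIP, INPUT) × 2 replicates.
Counts are negative-binomial (dispersion 0.1; NB is the field's default for
overdispersed read counts — the emulated assay publishes no count model).
Planted windows draw CLIP counts at `enrichment × input_mean` (default
4 × 15) in WT and C130Y and only residual signal (0.2 × input mean) in the
ΔRRM/IgG controls, which cannot bind RNA specifically. "Sticky" background
windows, placed on 20% of non-target genes, are enriched in *every* sample
— that is what makes them background: they pass the thresholds in the
controls too, and background subtraction removes them. A per-locus
expression factor (log-normal, median 1, sdlog 0.5) multiplies both CLIP and
INPUT means and is shared across all libraries at a locus; it models
transcript-abundance spread, and is what makes replicate cluster intensities
correlate strongly (r ≈ 0.7 on log2 counts) as in real replicate pairs,
while leaving the enrichment ratio untouched. Reads tile each window at
evenly spaced starts, so overlap-merging reconstructs the planted interval
exactly and read counts are conserved into cluster counts; all randomness
sits in the NB draws. One global seed expands into substreams (genome =
seed, counts = seed + 1) so stages regenerate independently.

What the generator does *not* emulate: crosslink-site nucleotide bias, PCR
duplication and mappability artifacts, 5′ read-end pile-up shapes, and any
correlation between UTR features and binding strength. Passing tests
therefore certify the *rules* — thresholding, matching, subtraction,
annotation arithmetic — not the biology of any particular dataset;
headline counts from real data (numbers of footprints and target genes)
depend on the deposited libraries and genome resources and are not
reproduced here.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; GFF/GTF are converted on
  read, BED written natively. IRanges/GenomicRanges do the interval algebra
  behind two conversion shims.
* CDS is taken to include the stop codon; `stop_codon_pos` is the first base
  of the last in-frame codon.
* Empty read libraries cluster to empty tables (not errors); empty
  background sets are the identity for subtraction; empty footprint sets
  give all-zero metagene profiles. Zero or negative library sizes, groups
  smaller than two, regions with fewer than three samples, and a
  non-positive monosome area are errors.
* All tie-breaks (longest isoform, largest overlap) fall back to
  lexicographic ids, so identical inputs give byte-identical outputs.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
recovery experiments use 260 genes with 200 planted sites across five seeds;
UTR statistics use 2150 genes (150 targets vs ~2000 background); oracle
equivalence uses 30 randomized fixtures of ≤ 100 clusters checked against
literal brute-force filters; traces are sampled at ≥ 10 points per Gaussian
sigma. These sizes give stable statistics while keeping a full run fast.

## Known limitations

The clustering stage is a stand-in for an external peak caller: it is a
deterministic overlap-merge, not a statistical model of crosslink pile-ups,
and `read_cluster_table` exists precisely so externally called clusters can
be substituted. Footprint-level (not read-level) metagene coverage slightly
smooths sub-cluster structure. The Mann-Whitney normal approximation is
used for all large samples; for heavily tied small samples the exact method
is unavailable (as in `wilcox.test`). RNA secondary structure and
conservation are out of scope; externally computed values can be carried as
metadata but are never recomputed.
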