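# seclipr

An R package for calling protein–RNA **footprints** from mapped seCLIP
(single-end enhanced crosslinking and immunoprecipitation) data and for
characterising the 5′UTRs those footprints occupy — the analysis style used to
map where a translation-initiation factor sits on neuronal mRNAs, together
with Simpson's-rule quantification of polysome gradient traces.

## Who it is for

Anyone with mapped CLIP/INPUT read intervals (or pre-built read clusters), a
genome annotation and a genome FASTA, who wants a transparent, fully tested
implementation of the fixed-threshold footprint definition used in seCLIP
analyses of neuronal RNA-binding proteins, plus the downstream 5′UTR feature
statistics. A synthetic-data generator with known ground truth makes every
stage testable without any sequencing data.

## The method

**Footprint calling.** Reads of each CLIP replicate are merged into maximal
clusters (same strand, overlap or book-ended). Clusters are overlap-matched
across the two biological replicates; a consensus cluster is retained as a
footprint iff

* it is detected (≥ 1 read) in **both** replicates, and
* in at least one replicate it has **≥ 20 reads** and
  **≥ 1.5-fold** RPM enrichment over the paired INPUT control, computed on a
  common window:

  FC = (RPM_CLIP + c) / (RPM_INPUT + c),  RPM = count / library size × 10⁶,

  with pseudocount c = 1 RPM. Both thresholds are inclusive. Footprints
  passing the same rule in the IgG (no transgene) and ΔRRM (RNA-binding-dead)
  controls are background and are subtracted by ≥ 1 bp same-strand overlap.

**Feature annotation.** Footprints overlapping a 5′UTR *or CDS* are grouped
into one category, *5′UTR proximal* (CDS clusters almost always sit within
~200 nt of a 5′UTR); then 3′UTR, intron, non-coding, intergenic, in that
precedence. Start/stop-codon-anchored metagene profiles accumulate each
footprint's RPM over the transcript-space (spliced) offsets it covers.

**5′UTR features.** 5′UTRs are extracted per gene (≥ 10 nt, longest isoform
per gene), with total %GC and %GC in 10-nt bins counted back from the ATG.
Target-vs-background comparisons of length and GC use the two-sided
Mann-Whitney test; trans-splice tables are joined to report the percentage of
targets annotated as SL trans-spliced.

**Polysome profiling.** Absorbance traces are integrated with composite
Simpson's rule over user-supplied monosome (80S) and polysome regions, and
summarised as the polysome:monosome (P/M) area ratio.

## Worked example

```r
library(seclipr)

# simulate a genome with 200 planted 5'UTR-proximal binding sites,
# 4x CLIP enrichment over an INPUT mean of 15 reads, two replicates
cfg <- simulation_config(seed = 1, n_genes = 260, n_target_genes = 200,
                         enrichment = 4, input_mean = 15)
sim  <- simulate_genome(cfg)
libs <- simulate_clip(sim)$libraries

call <- function(s) call_footprints(libs[[s]]$CLIP, libs[[s]]$INPUT,
                                    footprint_config(), sample = s)
specific <- subtract_background(call("WT"), call("dRRM"), call("IgG"))
footprint_recovery(specific, sim$truth$footprints)
#> $recall    0.985       # planted sites recovered at the 20-read / 1.5-fold rule
#> $precision 1           # every surviving call is a planted site
#> $n_called  197
#> $n_truth   200

specific <- annotate_footprints(specific, sim$annotation)
category_proportions(specific)
#>              category count fraction
#> 1 five_prime_proximal   197        1

utrs <- extract_five_prime_utrs(sim$annotation, sim$sequences)
targets <- utrs[utrs$gene_id %in% specific$gene_id, ]
background <- utrs[!utrs$gene_id %in% specific$gene_id, ]
compare_utr_feature(targets, background, "gc")
#> Mann-Whitney (gc): targets n=197 median=41.75 vs background n=63 median=37.61;
#> U=8269.5, two-sided p=7.14e-05
```

The recall/precision say that, under the generator's study conditions, the
retention rule recovers planted binding sites almost perfectly while
background subtraction removes sticky (control-enriched) clusters; the GC
comparison shows the planted targets' GC-rich 5′UTRs separating from the
background population.

A polysome trace in three lines:

```r
st <- simulate_polysome_trace(
  peaks = data.frame(center = c(2, 6), amplitude = c(1.5, 1.5), width = c(0.25, 0.5)),
  span = c(0, 10), step = 0.025,
  regions = list(monosome_80S = c(0.5, 3.5), polysome = c(4.5, 9)))
pm_ratio(st$trace)
#> [1] 1.997   # analytic ratio of the two Gaussian areas is 2
```

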