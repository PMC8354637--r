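#' Construct a sample library of mapped read intervals
#'
#' @param sample sample label, e.g. \code{"WT_CLIP"} or \code{"IgG_INPUT"}.
#' @param replicate biological replicate number (>= 1).
#' @param reads BED-like data.frame of read intervals
#'   (\code{chrom,start,end,strand}).
#' @param total_mapped_reads library size (total uniquely mapped reads); must
#'   be >= \code{nrow(reads)}.
#' @return object of class \code{sample_library}.
#' @export
sample_library <- function(sample, replicate, reads, total_mapped_reads) {
  validate_intervals(reads)
  stopifnot(replicate >= 1, total_mapped_reads > 0)
  if (total_mapped_reads < nrow(reads))
    stop("total_mapped_reads (", total_mapped_reads,
         ") is smaller than the number of reads (", nrow(reads), ")")
  structure(list(sample = sample, replicate = as.integer(replicate),
                 reads = reads, total_mapped_reads = total_mapped_reads),
            class = "sample_library")
}

#' @export
print.sample_library <- function(x, ...) {
  cat("sample_library", x$sample, "rep", x$replicate, "-", nrow(x$reads),
      "reads /", x$total_mapped_reads, "mapped\n")
  invisible(x)
}

#' Merge overlapping reads into clusters
#'
#' Same-strand reads whose intervals overlap, abut, or lie within
#' \code{min_gap} bases of each other are merged into one maximal cluster
#' (the bedtools \code{merge -d} convention). The cluster's \code{count} is
#' its number of constituent reads, so cluster counts sum to the number of
#' input reads.
#'
#' @param library a \code{sample_library}, or a bare BED-like read data.frame.
#' @param min_gap maximum gap (nt) between merged reads; default 0 (overlap or
#'   book-ended).
#' @return data.frame \code{chrom,start,end,strand,count}, sorted; empty input
#'   gives an empty frame.
#' @export
build_clusters <- function(library, min_gap = 0) {
  reads <- if (inherits(library, "sample_library")) library$reads else library
  validate_intervals(reads)
  if (nrow(reads) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      count = numeric(0)))
  red <- GenomicRanges::reduce(as_granges(reads), min.gapwidth = min_gap + 1,
                               with.revmap = TRUE, ignore.strand = FALSE)
  out <- granges_to_bed(red)
  out$count <- lengths(red$revmap)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads-per-million normalisation
#'
#' @param count read count (vectorised).
#' @param library_size total mapped reads of the library (> 0).
#' @return \code{count / library_size * 1e6}.
#' @export
rpm <- function(count, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count / library_size * 1e6
}

## count reads of `reads` overlapping (>=1 bp, same strand) each interval
count_overlapping_reads <- function(intervals, reads) {
  n <- nrow(intervals)
  counts <- numeric(n)
  if (n == 0 || nrow(reads) == 0) return(counts)
  hits <- overlap_pairs(intervals, reads)
  tab <- table(hits$query)
  counts[as.integer(names(tab))] <- as.vector(tab)
  counts
}

## match two per-replicate cluster sets: reduce the union of intervals into
## consensus regions; per region, sum the counts of each replicate's clusters
## falling in it. Returns chrom,start,end,strand,count1,count2.
match_replicate_clusters <- function(cl1, cl2) {
  both <- rbind(cl1[, c("chrom", "start", "end", "strand")],
                cl2[, c("chrom", "start", "end", "strand")])
  if (nrow(both) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      count1 = numeric(0), count2 = numeric(0)))
  cons <- granges_to_bed(GenomicRanges::reduce(as_granges(both),
                                               ignore.strand = FALSE))
  sum_in <- function(cl) {
    out <- numeric(nrow(cons))
    if (nrow(cl) == 0) return(out)
    h <- overlap_pairs(cons, cl)
    s <- tapply(cl$count[h$subject], h$query, sum)
    out[as.integer(names(s))] <- as.vector(s)
    out
  }
  cons$count1 <- sum_in(cl1)
  cons$count2 <- sum_in(cl2)
  cons <- cons[order(cons$chrom, cons$start, cons$strand), , drop = FALSE]
  rownames(cons) <- NULL
  cons
}

#' Replicate agreement of cluster read counts
#'
#' Pearson correlation of log2(count + 1) between two biological replicates,
#' computed over consensus clusters detected (count >= 1) in both replicates.
#' Overlapping clusters from the two replicates are unioned into consensus
#' intervals before comparison.
#'
#' @param clusters1,clusters2 per-replicate cluster frames from
#'   [build_clusters()].
#' @return list with \code{r} (Pearson correlation on the log scale) and
#'   \code{n_shared} (number of clusters detected in both replicates).
#' @export
replicate_correlation <- function(clusters1, clusters2) {
  cons <- match_replicate_clusters(clusters1, clusters2)
  shared <- cons[cons$count1 >= 1 & cons$count2 >= 1, , drop = FALSE]
  if (nrow(shared) < 2)
    stop("fewer than 2 clusters shared between replicates; ",
         "correlation undefined")
  r <- stats::cor(log2(shared$count1 + 1), log2(shared$count2 + 1),
                  method = "pearson")
  list(r = r, n_shared = nrow(shared))
}

#' Write a cluster table as TSV
#' @param clusters cluster frame from [build_clusters()].
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cluster table (TSV from [write_cluster_table()] or BED with the
#' count in the score column)
#' @param path input path.
#' @return cluster frame \code{chrom,start,end,strand,count}.
#' @export
read_cluster_table <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read_bed(path)
    out <- bed[, c("chrom", "start", "end", "strand")]
    out$count <- bed$score
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  validate_intervals(out)
  out
}
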