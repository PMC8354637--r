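#' Construct a table of genomic intervals
#'
#' Intervals are kept in the BED convention throughout the package: 0-based
#' start, exclusive end, strand one of \code{"+"} or \code{"-"}. GFF/GTF input
#' is converted to this convention on read.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy \code{start < end}.
#' @param strand character vector of \code{"+"} / \code{"-"}.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @export
genomic_intervals <- function(chrom, start, end, strand) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(df)
}

## 0-based half-open data.frame -> GRanges (1-based closed), and back.
## All IRanges/GenomicRanges machinery is called through these two shims so
## the coordinate convention changes in exactly one place.
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
}

granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

## Strand-aware overlap pairs between two BED-like frames.
## Returns a data.frame (query, subject, overlap_bp); >= 1 bp overlap only.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = numeric(0)))
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                      ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) - pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, overlap_bp = ov)
}

#' Read a BED6 file of intervals
#'
#' @param path path to a BED file (at least 6 columns).
#' @return data.frame with \code{chrom,start,end,name,score,strand}.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_bed(gr)
  out$name <- if (!is.null(gr$name)) gr$name else NA_character_
  out$score <- if (!is.null(gr$score)) gr$score else NA_real_
  out[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Write intervals as BED6
#'
#' @param df data.frame with \code{chrom,start,end,strand} and optionally
#'   \code{name} and \code{score} columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  gr <- as_granges(df)
  gr$name <- if (!is.null(df$name)) df$name else "."
  gr$score <- if (!is.null(df$score)) df$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
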