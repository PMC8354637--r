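#' Extract 5'UTR records from an annotation and genome sequence
#'
#' Applies the study's selection rule for 5'UTR feature analysis: only UTRs of
#' at least \code{min_len} nucleotides are considered, and (by default) only
#' the longest 5'UTR isoform of each gene is retained so that no gene is
#' counted twice. The returned sequence is the spliced (intron-free) UTR in
#' 5' to 3' orientation, ending immediately before the start-codon ATG;
#' minus-strand UTRs are reverse-complemented.
#'
#' @param annotation a \code{genome_annotation} from [load_annotation()].
#' @param sequences genome sequence: a \code{Biostrings::DNAStringSet} or a
#'   path to a FASTA file.
#' @param min_len minimum UTR length in nt (inclusive threshold; default 10).
#' @param longest_per_gene keep only the longest qualifying isoform per gene
#'   (ties broken by lexicographically smallest transcript_id).
#' @param trans_splice optional trans-splice table (see
#'   [read_trans_splice_table()]); genes present in it are flagged
#'   \code{trans_spliced}.
#' @param strip_sl optional spliced-leader sequence; when supplied, a UTR whose
#'   5' end begins with this sequence has it removed before length/GC
#'   computation and is flagged \code{sl_excluded}.
#' @return a \code{data.frame} of class \code{utr_records} with columns
#'   \code{gene_id, transcript_id, length, sequence, gc_fraction,
#'   trans_spliced, sl_excluded}.
#' @export
extract_five_prime_utrs <- function(annotation, sequences, min_len = 10,
                                    longest_per_gene = TRUE,
                                    trans_splice = NULL, strip_sl = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::readDNAStringSet(sequences)
  seqnames <- sub("\\s.*$", "", names(sequences))
  names(sequences) <- seqnames

  txs <- annotation$transcripts
  need <- unique(vapply(txs, `[[`, character(1), "chrom"))
  missing <- setdiff(need, seqnames)
  if (length(missing))
    stop("chromosome(s) missing from FASTA: ", paste(missing, collapse = ", "))

  spliced <- vapply(txs, function(tx) {
    if (nrow(tx$utr5) == 0) return(NA_character_)
    utr_sequence(tx, sequences)
  }, character(1))

  rec <- data.frame(
    gene_id = vapply(txs, `[[`, character(1), "gene_id"),
    transcript_id = vapply(txs, `[[`, character(1), "transcript_id"),
    sequence = unname(spliced),
    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$sequence), , drop = FALSE]

  sl_excluded <- rep(FALSE, nrow(rec))
  if (!is.null(strip_sl) && nzchar(strip_sl) && nrow(rec) > 0) {
    has_sl <- startsWith(toupper(rec$sequence), toupper(strip_sl))
    rec$sequence[has_sl] <- substring(rec$sequence[has_sl], nchar(strip_sl) + 1)
    sl_excluded <- has_sl
  }
  rec$length <- nchar(rec$sequence)
  rec$sl_excluded <- sl_excluded

  keep <- rec$length >= min_len
  rec <- rec[keep, , drop = FALSE]

  if (longest_per_gene && nrow(rec) > 0) {
    rec <- rec[order(rec$gene_id, -rec$length, rec$transcript_id), , drop = FALSE]
    rec <- rec[!duplicated(rec$gene_id), , drop = FALSE]
  }

  rec$gc_fraction <- if (nrow(rec)) vapply(rec$sequence, gc_content, numeric(1),
                                           USE.NAMES = FALSE) else numeric(0)
  spliced_genes <- if (is.null(trans_splice)) character(0) else
    unique(trans_splice$gene_id)
  rec$trans_spliced <- rec$gene_id %in% spliced_genes
  rec <- rec[, c("gene_id", "transcript_id", "length", "sequence",
                 "gc_fraction", "trans_spliced", "sl_excluded")]
  rownames(rec) <- NULL
  class(rec) <- c("utr_records", "data.frame")
  rec
}

## genomic 0-based positions of a transcript's 5'UTR bases, in 5'->3' order
utr5_positions <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$utr5)), function(i)
    seq(tx$utr5$start[i], tx$utr5$end[i] - 1)))
  if (tx$strand == "-") rev(pos) else pos
}

utr_sequence <- function(tx, sequences) {
  chromseq <- sequences[[tx$chrom]]
  if (max(tx$utr5$end) > length(chromseq))
    stop("UTR interval of transcript '", tx$transcript_id,
         "' extends beyond the end of chromosome '", tx$chrom, "'")
  parts <- Biostrings::DNAStringSet(
    lapply(seq_len(nrow(tx$utr5)), function(i)
      Biostrings::subseq(chromseq, tx$utr5$start[i] + 1, tx$utr5$end[i])))
  s <- Reduce(Biostrings::xscat, parts)
  if (tx$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' GC content of a nucleotide sequence
#'
#' @param sequence non-empty string over A,C,G,T,U (case-insensitive).
#' @param n_tolerant when TRUE, N is accepted and counted as non-GC (and the
#'   N fraction is attached as attribute \code{n_fraction}); otherwise any
#'   character outside ACGTU is an error naming its position.
#' @return fraction of G+C in \[0, 1\].
#' @export
gc_content <- function(sequence, n_tolerant = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  allowed <- c("A", "C", "G", "T", "U", if (n_tolerant) "N")
  bad <- which(!(chars %in% allowed))
  if (length(bad))
    stop("disallowed character '", chars[bad[1]], "' at position ", bad[1])
  gc <- sum(chars == "G" | chars == "C") / length(chars)
  if (n_tolerant)
    attr(gc, "n_fraction") <- sum(chars == "N") / length(chars)
  gc
}

#' Positional GC content in bins counted back from the start codon
#'
#' Bin 1 covers the \code{bin_size} bases immediately 5' of the ATG, bin 2 the
#' next \code{bin_size} bases further 5', and so on; the final (most 5') bin
#' may be partial and reports its true length. The length-weighted mean of the
#' bin GC values equals the total GC of the sequence.
#'
#' @param utr a UTR sequence string (5' to 3', ending just before the ATG) or
#'   a single \code{utr_records} row.
#' @param bin_size bin width in nt (default 10).
#' @return data.frame with columns \code{bin} (1 = adjacent to ATG),
#'   \code{length}, \code{gc}.
#' @export
binned_gc <- function(utr, bin_size = 10) {
  if (is.data.frame(utr) || is.list(utr)) utr <- utr$sequence
  stopifnot(is.character(utr), length(utr) == 1, nzchar(utr))
  if (bin_size < 1) stop("bin_size must be >= 1")
  chars <- strsplit(toupper(utr), "", fixed = TRUE)[[1]]
  n <- length(chars)
  ## distance from ATG: last character is 1 nt 5' of ATG
  dist <- rev(seq_len(n))
  bin <- ceiling(dist / bin_size)
  is_gc <- chars == "G" | chars == "C"
  f <- factor(bin, levels = sort(unique(bin)))  # keep numeric, not lexical, order
  out <- data.frame(
    bin = sort(unique(bin)),
    length = as.vector(table(f)),
    gc = as.vector(tapply(is_gc, f, mean)))
  rownames(out) <- NULL
  out
}

#' Write a UTR feature table as TSV
#'
#' @param records a \code{utr_records} data.frame.
#' @param path output path.
#' @export
write_utr_table <- function(records, path) {
  out <- data.frame(gene_id = records$gene_id,
                    transcript_id = records$transcript_id,
                    length = records$length,
                    gc_percent = round(100 * records$gc_fraction, 4),
                    trans_spliced = records$trans_spliced)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
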