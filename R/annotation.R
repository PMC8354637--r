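#' Load a genome annotation from GFF3 or GTF
#'
#' Builds per-transcript gene models (exons, CDS, UTRs, start/stop codon
#' positions) from a GFF3 or GTF file. When 5'/3'UTRs are not annotated
#' explicitly they are derived from exon/CDS geometry: UTR5 is the exonic
#' sequence strictly 5' of the CDS (strand-aware), UTR3 the exonic sequence
#' strictly 3' of it. All coordinates are converted to the package's 0-based
#' half-open convention on read.
#'
#' The CDS is assumed to include the stop codon (GFF3/WormBase convention);
#' \code{stop_codon_pos} is the genomic coordinate of the first base of the
#' last in-frame codon.
#'
#' @param path path to the annotation file.
#' @param dialect \code{"gff3"} or \code{"gtf"}; default guessed from the file
#'   extension.
#' @return an object of class \code{genome_annotation}: a list with
#'   \code{transcripts} (named list of transcript models) and \code{genes}
#'   (named list mapping gene_id to its transcript_ids).
#' @export
load_annotation <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  dialect <- match.arg(tolower(dialect), c("gff3", "gtf"))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gtf") "GTF" else "GFF3"),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e)))
  feat <- granges_to_bed(gr)
  feat$type <- tolower(as.character(gr$type))

  if (dialect == "gtf") {
    feat$transcript_id <- as.character(gr$transcript_id)
    feat$gene_id <- as.character(gr$gene_id)
  } else {
    ids <- as.character(gr$ID)
    parents <- vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    ## map each sub-feature to its transcript; transcripts to their gene
    tx_types <- c("mrna", "transcript", "ncrna", "lncrna", "snorna", "snrna",
                  "trna", "rrna", "mirna", "pseudogenic_transcript")
    is_tx <- feat$type %in% tx_types
    tx_gene <- stats::setNames(parents[is_tx], ids[is_tx])
    tx_gene[is.na(tx_gene)] <- names(tx_gene)[is.na(tx_gene)]
    feat$transcript_id <- ifelse(is_tx, ids, parents)
    feat$gene_id <- ifelse(is_tx, unname(tx_gene),
                           unname(tx_gene[parents]))
  }

  keep_types <- c("exon", "cds", "five_prime_utr", "three_prime_utr")
  feat$type[feat$type == "five_prime_utr" | feat$type == "5utr"] <- "five_prime_utr"
  parts <- feat[feat$type %in% keep_types & !is.na(feat$transcript_id), ]
  if (nrow(parts) == 0)
    stop("annotation '", path, "' contains no exon/CDS features with ",
         "transcript attributes")

  transcripts <- lapply(split(parts, parts$transcript_id), build_transcript_model)
  genes <- split(vapply(transcripts, `[[`, character(1), "transcript_id"),
                 vapply(transcripts, `[[`, character(1), "gene_id"))
  genes <- lapply(genes, unname)
  structure(list(transcripts = transcripts, genes = genes),
            class = "genome_annotation")
}

## one transcript's features (BED frame with type/transcript_id/gene_id) ->
## transcript model list
build_transcript_model <- function(df) {
  txid <- df$transcript_id[1]
  gid <- df$gene_id[1]
  if (is.na(gid)) gid <- txid
  strand <- df$strand[1]
  chrom <- df$chrom[1]
  take <- function(type) {
    x <- df[df$type == type, c("chrom", "start", "end", "strand")]
    x <- x[order(x$start), , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  exons <- take("exon")
  cds <- take("cds")
  if (nrow(exons) == 0) {
    if (nrow(cds) > 0)
      stop("transcript '", txid, "' has CDS but no exons")
    exons <- take("five_prime_utr")  # degenerate; rarely hit
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("transcript '", txid, "' has overlapping exons")

  utr5 <- take("five_prime_utr")
  utr3 <- take("three_prime_utr")
  start_codon_pos <- NA_real_
  stop_codon_pos <- NA_real_
  if (nrow(cds) > 0) {
    cmin <- min(cds$start); cmax <- max(cds$end)
    if (strand == "+") {
      start_codon_pos <- cmin
      stop_codon_pos <- cmax - 3
      if (nrow(utr5) == 0) utr5 <- clip_intervals(exons, -Inf, cmin)
      if (nrow(utr3) == 0) utr3 <- clip_intervals(exons, cmax, Inf)
    } else {
      start_codon_pos <- cmax - 1
      stop_codon_pos <- cmin + 2
      if (nrow(utr5) == 0) utr5 <- clip_intervals(exons, cmax, Inf)
      if (nrow(utr3) == 0) utr3 <- clip_intervals(exons, -Inf, cmin)
    }
  }
  list(gene_id = gid, transcript_id = txid, chrom = chrom, strand = strand,
       exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
       start_codon_pos = start_codon_pos, stop_codon_pos = stop_codon_pos)
}

## restrict a sorted exon frame to [lo, hi) (genomic coordinates)
clip_intervals <- function(exons, lo, hi) {
  s <- pmax(exons$start, lo)
  e <- pmin(exons$end, hi)
  keep <- s < e
  out <- exons[keep, , drop = FALSE]
  out$start <- s[keep]
  out$end <- e[keep]
  rownames(out) <- NULL
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$transcripts), "transcripts,",
      length(x$genes), "genes\n")
  invisible(x)
}

utr5_length <- function(tx) {
  if (nrow(tx$utr5) == 0) 0 else sum(tx$utr5$end - tx$utr5$start)
}

## one transcript per gene: longest 5'UTR, ties broken by lexicographically
## smallest transcript_id (deterministic)
select_anchored_transcripts <- function(annotation) {
  vapply(annotation$genes, function(txids) {
    lens <- vapply(txids, function(t) utr5_length(annotation$transcripts[[t]]),
                   numeric(1))
    cand <- sort(txids[lens == max(lens)])
    cand[1]
  }, character(1))
}
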