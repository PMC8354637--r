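## feature index: per-category BED frames with a gene_id column.
## five_prime_proximal groups 5'UTR and CDS into one category, matching the
## observation that CDS clusters almost always sit within ~200 nt of a 5'UTR.
feature_index <- function(annotation) {
  txs <- annotation$transcripts
  grab <- function(field, coding) {
    pieces <- lapply(txs, function(tx) {
      if (coding && nrow(tx$cds) == 0) return(NULL)
      if (!coding && nrow(tx$cds) > 0) return(NULL)
      x <- tx[[field]]
      if (nrow(x) == 0) return(NULL)
      x$gene_id <- tx$gene_id
      x
    })
    out <- do.call(rbind, pieces)
    if (is.null(out))
      out <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0),
                        gene_id = character(0))
    rownames(out) <- NULL
    out
  }
  introns <- do.call(rbind, lapply(txs, function(tx) {
    if (nrow(tx$exons) < 2) return(NULL)
    data.frame(chrom = tx$chrom,
               start = tx$exons$end[-nrow(tx$exons)],
               end = tx$exons$start[-1],
               strand = tx$strand, gene_id = tx$gene_id)
  }))
  if (is.null(introns))
    introns <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          gene_id = character(0))
  proximal <- rbind(grab("utr5", coding = TRUE), grab("cds", coding = TRUE))
  list(five_prime_proximal = proximal,
       three_prime_utr = grab("utr3", coding = TRUE),
       intron = introns,
       non_coding = grab("exons", coding = FALSE))
}

#' Assign footprints to gene-feature categories
#'
#' Categories in precedence order: \code{five_prime_proximal} (overlap with
#' any 5'UTR or CDS — the two are grouped into one category),
#' \code{three_prime_utr}, \code{intron}, \code{non_coding} (exons of
#' transcripts without a CDS), else \code{intergenic}. Each footprint gets
#' exactly one label. The assigned \code{gene_id} is the gene with the
#' largest base overlap within the winning category (ties broken by the
#' lexicographically smaller gene_id).
#'
#' @param footprints a \code{footprints} frame (any BED-like frame works).
#' @param annotation a \code{genome_annotation}.
#' @return the input with \code{category} and \code{gene_id} columns filled.
#' @export
annotate_footprints <- function(footprints, annotation) {
  fp <- as.data.frame(footprints)
  idx <- feature_index(annotation)
  n <- nrow(fp)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  assigned <- rep(FALSE, n)
  for (cat_name in names(idx)) {
    feats <- idx[[cat_name]]
    if (nrow(feats) == 0 || all(assigned)) next
    hits <- overlap_pairs(fp, feats)
    hits <- hits[!assigned[hits$query], , drop = FALSE]
    if (nrow(hits) == 0) next
    hits$gene <- feats$gene_id[hits$subject]
    agg <- stats::aggregate(overlap_bp ~ query + gene, data = hits, FUN = sum)
    agg <- agg[order(agg$query, -agg$overlap_bp, agg$gene), , drop = FALSE]
    best <- agg[!duplicated(agg$query), , drop = FALSE]
    category[best$query] <- cat_name
    gene_id[best$query] <- best$gene
    assigned[best$query] <- TRUE
  }
  footprints$category <- category
  footprints$gene_id <- gene_id
  footprints
}

#' Footprint counts and fractions per feature category
#'
#' @param footprints annotated \code{footprints} (with a \code{category}
#'   column).
#' @return data.frame \code{category, count, fraction}; fractions sum to 1.
#' @export
category_proportions <- function(footprints) {
  if (nrow(footprints) == 0) stop("no footprints to tally")
  if (is.null(footprints$category)) stop("footprints lack a 'category' column")
  tab <- table(footprints$category)
  out <- data.frame(category = names(tab), count = as.vector(tab),
                    fraction = as.vector(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$category), , drop = FALSE]
}

## genomic 0-based positions -> transcript-space 0-based coordinates
## (0 = transcript 5' end); NA for non-exonic positions
tx_coord <- function(tx, pos) {
  ex <- tx$exons
  widths <- ex$end - ex$start
  out <- rep(NA_real_, length(pos))
  if (tx$strand == "+") {
    cum <- cumsum(c(0, widths[-length(widths)]))
    for (i in seq_len(nrow(ex))) {
      in_ex <- pos >= ex$start[i] & pos < ex$end[i]
      out[in_ex] <- cum[i] + pos[in_ex] - ex$start[i]
    }
  } else {
    ord <- rev(seq_len(nrow(ex)))  # rightmost exon is transcript 5'
    cum <- cumsum(c(0, widths[ord][-length(widths)]))
    for (k in seq_along(ord)) {
      i <- ord[k]
      in_ex <- pos >= ex$start[i] & pos < ex$end[i]
      out[in_ex] <- cum[k] + ex$end[i] - 1 - pos[in_ex]
    }
  }
  out
}

#' Metagene coverage anchored at the start or stop codon
#'
#' For each annotated footprint, every transcript-space base it covers inside
#' the window contributes the footprint's RPM to that offset. Offsets are
#' spliced (intron-free) distances from the anchor, strand-aware: offset 0 is
#' the first base of the anchor codon and negative offsets are 5' of it. The
#' anchored transcript of a gene is the one with the longest 5'UTR (the same
#' selection used for UTR extraction).
#'
#' @param footprints annotated \code{footprints} with \code{gene_id} and
#'   \code{rpm} columns.
#' @param annotation a \code{genome_annotation}.
#' @param anchor \code{"start"} or \code{"stop"} codon.
#' @param window two non-negative numbers \code{c(w1, w2)}: offsets span
#'   \code{-w1 .. +w2} (default 300, 300).
#' @return object of class \code{metagene_profile}: list with \code{anchor},
#'   \code{offsets}, \code{coverage} (cumulative RPM per offset) and
#'   \code{n_footprints} used.
#' @export
metagene_coverage <- function(footprints, annotation,
                              anchor = c("start", "stop"),
                              window = c(300, 300)) {
  anchor <- match.arg(anchor)
  stopifnot(length(window) == 2, all(window >= 0))
  offsets <- seq(-window[1], window[2])
  coverage <- numeric(length(offsets))
  anchored <- select_anchored_transcripts(annotation)
  fp <- as.data.frame(footprints)
  if (is.null(fp$rpm)) stop("footprints lack an 'rpm' column")
  used <- 0L
  for (i in seq_len(nrow(fp))) {
    gid <- fp$gene_id[i]
    if (is.na(gid) || !gid %in% names(anchored)) next
    tx <- annotation$transcripts[[anchored[[gid]]]]
    anchor_pos <- if (anchor == "start") tx$start_codon_pos else tx$stop_codon_pos
    if (is.na(anchor_pos)) {
      warning("footprint on gene '", gid,
              "' skipped: anchored transcript has no ", anchor, " codon")
      next
    }
    anchor_tx <- tx_coord(tx, anchor_pos)
    base_tx <- tx_coord(tx, seq(fp$start[i], fp$end[i] - 1))
    off <- base_tx[!is.na(base_tx)] - anchor_tx
    off <- off[off >= -window[1] & off <= window[2]]
    if (length(off)) {
      coverage[off + window[1] + 1] <- coverage[off + window[1] + 1] + fp$rpm[i]
      used <- used + 1L
    }
  }
  structure(list(anchor = anchor, offsets = offsets, coverage = coverage,
                 n_footprints = used),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile anchored at the", x$anchor, "codon:",
      length(x$offsets), "offsets,", x$n_footprints,
      "footprints, total RPM*nt =", sum(x$coverage), "\n")
  invisible(x)
}

#' @method as.data.frame metagene_profile
#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(offset = x$offsets, rpm = x$coverage)
}

#' @method plot metagene_profile
#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$coverage, type = "l",
                 xlab = sprintf("distance from %s codon (nt)", x$anchor),
                 ylab = "cumulative coverage (RPM)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Write a metagene profile as TSV (offset, rpm)
#' @param profile a \code{metagene_profile}.
#' @param path output path.
#' @export
write_metagene_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
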