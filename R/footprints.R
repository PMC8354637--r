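#' Footprint-calling configuration
#'
#' The retention rule: a read cluster is a footprint when it is detected
#' (>= 1 read) in both biological replicates and, in at least one replicate,
#' carries at least \code{min_reads} reads with at least \code{min_fc}-fold
#' RPM enrichment over the paired INPUT control. Both thresholds are
#' inclusive. \code{threshold_scope = "both_replicates"} instead requires the
#' count/enrichment thresholds in every replicate.
#'
#' @param min_reads minimum cluster read count (default 20).
#' @param min_fc minimum CLIP/INPUT fold change (default 1.5).
#' @param pseudocount pseudocount in RPM units added to numerator and
#'   denominator of the fold change (default 1).
#' @param require_both_replicates require cluster presence in both replicates
#'   (default TRUE).
#' @param threshold_scope \code{"either_replicate"} (default) or
#'   \code{"both_replicates"}: where the count/enrichment thresholds must hold.
#' @return object of class \code{footprint_config}.
#' @export
footprint_config <- function(min_reads = 20, min_fc = 1.5, pseudocount = 1,
                             require_both_replicates = TRUE,
                             threshold_scope = c("either_replicate",
                                                 "both_replicates")) {
  threshold_scope <- match.arg(threshold_scope)
  stopifnot(min_reads >= 0, min_fc > 0, pseudocount > 0)
  structure(list(min_reads = min_reads, min_fc = min_fc,
                 pseudocount = pseudocount,
                 require_both_replicates = require_both_replicates,
                 threshold_scope = threshold_scope),
            class = "footprint_config")
}

#' CLIP over INPUT enrichment fold change
#'
#' @param clip_rpm,input_rpm RPM values (>= 0), vectorised.
#' @param pseudocount pseudocount in RPM units (> 0).
#' @return \code{(clip_rpm + pseudocount) / (input_rpm + pseudocount)}.
#' @export
enrichment_fc <- function(clip_rpm, input_rpm, pseudocount = 1) {
  if (any(clip_rpm < 0) || any(input_rpm < 0)) stop("RPM values must be >= 0")
  if (any(pseudocount <= 0)) stop("pseudocount must be > 0")
  (clip_rpm + pseudocount) / (input_rpm + pseudocount)
}

#' Call footprints from CLIP and INPUT libraries
#'
#' Clusters are built per CLIP replicate by overlap merging, then
#' overlap-matched across replicates; the emitted interval is the union of
#' the matched replicate clusters. For each replicate the INPUT read count is
#' taken over the same consensus interval (reads of the replicate-matched
#' INPUT library overlapping it), so that enrichment is always computed on a
#' common window. The retention rule of [footprint_config()] is then applied.
#'
#' @param clip list of two \code{sample_library} objects (CLIP replicates 1
#'   and 2).
#' @param input list of two \code{sample_library} objects (replicate-matched
#'   INPUT controls).
#' @param config a \code{footprint_config}.
#' @param sample optional sample label stored on the result.
#' @return data.frame of class \code{footprints}: interval columns plus
#'   per-replicate \code{count}, \code{rpm}, \code{input_rpm}, \code{fc},
#'   the footprint RPM (\code{rpm}, mean of the replicate CLIP RPMs) and
#'   \code{passing_replicate} ("1", "2" or "both").
#' @export
call_footprints <- function(clip, input, config = footprint_config(),
                            sample = NA_character_) {
  if (length(clip) != 2 || length(input) != 2)
    stop("need exactly two CLIP and two INPUT replicate libraries")
  for (lib in c(clip, input))
    if (!inherits(lib, "sample_library"))
      stop("clip and input must be lists of sample_library objects")

  cl1 <- build_clusters(clip[[1]])
  cl2 <- build_clusters(clip[[2]])
  cons <- match_replicate_clusters(cl1, cl2)

  empty <- function() {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      count_rep1 = numeric(0), count_rep2 = numeric(0),
                      rpm_rep1 = numeric(0), rpm_rep2 = numeric(0),
                      input_rpm_rep1 = numeric(0), input_rpm_rep2 = numeric(0),
                      fc_rep1 = numeric(0), fc_rep2 = numeric(0),
                      rpm = numeric(0), passing_replicate = character(0),
                      sample = character(0))
    class(out) <- c("footprints", "data.frame")
    out
  }
  if (nrow(cons) == 0) return(empty())

  in_count1 <- count_overlapping_reads(cons, input[[1]]$reads)
  in_count2 <- count_overlapping_reads(cons, input[[2]]$reads)

  cons$rpm_rep1 <- rpm(cons$count1, clip[[1]]$total_mapped_reads)
  cons$rpm_rep2 <- rpm(cons$count2, clip[[2]]$total_mapped_reads)
  cons$input_rpm_rep1 <- rpm(in_count1, input[[1]]$total_mapped_reads)
  cons$input_rpm_rep2 <- rpm(in_count2, input[[2]]$total_mapped_reads)
  cons$fc_rep1 <- enrichment_fc(cons$rpm_rep1, cons$input_rpm_rep1,
                                config$pseudocount)
  cons$fc_rep2 <- enrichment_fc(cons$rpm_rep2, cons$input_rpm_rep2,
                                config$pseudocount)

  present <- if (config$require_both_replicates)
    cons$count1 >= 1 & cons$count2 >= 1 else cons$count1 + cons$count2 >= 1
  pass1 <- cons$count1 >= config$min_reads & cons$fc_rep1 >= config$min_fc
  pass2 <- cons$count2 >= config$min_reads & cons$fc_rep2 >= config$min_fc
  pass <- if (config$threshold_scope == "either_replicate")
    pass1 | pass2 else pass1 & pass2

  keep <- present & pass
  out <- cons[keep, , drop = FALSE]
  if (nrow(out) == 0) return(empty())
  names(out)[names(out) == "count1"] <- "count_rep1"
  names(out)[names(out) == "count2"] <- "count_rep2"
  out$rpm <- (out$rpm_rep1 + out$rpm_rep2) / 2
  out$passing_replicate <- ifelse(pass1[keep] & pass2[keep], "both",
                                  ifelse(pass1[keep], "1", "2"))
  out$sample <- sample
  rownames(out) <- NULL
  class(out) <- c("footprints", "data.frame")
  out
}

#' @export
print.footprints <- function(x, ...) {
  cat("footprints:", nrow(x), "intervals")
  if (nrow(x) && !all(is.na(x$sample)))
    cat(" (", paste(unique(stats::na.omit(x$sample)), collapse = ", "), ")",
        sep = "")
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Subtract background footprints
#'
#' A footprint is removed when its interval overlaps (>= 1 bp, same strand)
#' any footprint in any of the background sets (typically the IgG no-transgene
#' and the delta-RRM control immunoprecipitations). Survivors are returned
#' unchanged. An empty background set is legal and is the identity.
#'
#' @param footprints a \code{footprints} frame.
#' @param ... one or more background \code{footprints} frames (or BED-like
#'   interval frames).
#' @return the surviving footprints, same columns.
#' @export
subtract_background <- function(footprints, ...) {
  bgs <- list(...)
  if (nrow(footprints) == 0 || length(bgs) == 0) return(footprints)
  drop <- rep(FALSE, nrow(footprints))
  for (bg in bgs) {
    if (is.null(bg) || nrow(bg) == 0) next
    hits <- overlap_pairs(as.data.frame(footprints), as.data.frame(bg))
    drop[unique(hits$query)] <- TRUE
  }
  out <- footprints[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count footprints and target genes across samples
#'
#' Takes the union of footprints from one or more samples (e.g. WT and a
#' point mutant), merging intervals that overlap across samples so a shared
#' binding site is counted once, optionally restricted to one feature
#' category, and counts distinct genes. Footprints must already carry
#' \code{gene_id} (and \code{category}) columns from [annotate_footprints()].
#'
#' @param ... one or more annotated \code{footprints} frames.
#' @param category optional feature-category label to restrict to (e.g.
#'   \code{"five_prime_proximal"}).
#' @return list with \code{n_footprints} (merged intervals) and
#'   \code{n_genes} (distinct gene_ids, NA excluded with a warning).
#' @export
count_target_genes <- function(..., category = NULL) {
  sets <- list(...)
  all_fp <- do.call(rbind, lapply(sets, as.data.frame))
  if (!is.null(category)) {
    if (is.null(all_fp$category)) stop("footprints lack a 'category' column")
    all_fp <- all_fp[all_fp$category %in% category, , drop = FALSE]
  }
  if (nrow(all_fp) == 0) return(list(n_footprints = 0L, n_genes = 0L))
  merged <- granges_to_bed(GenomicRanges::reduce(as_granges(all_fp),
                                                 ignore.strand = FALSE))
  genes <- unique(all_fp$gene_id)
  if (anyNA(genes)) {
    warning("footprint(s) without an assigned gene counted as 'unassigned'")
    genes <- genes[!is.na(genes)]
  }
  list(n_footprints = nrow(merged), n_genes = length(genes))
}

#' Compare footprint signal between two samples
#'
#' Footprints of the two samples are matched by interval overlap (union of
#' both sets, reduced into consensus intervals); a footprint absent from one
#' sample contributes RPM 0 there before the pseudocount. Reported on the
#' log2(rpm + pseudocount) scale, as in CLIP scatter comparisons.
#'
#' @param fp_a,fp_b \code{footprints} frames of the two samples.
#' @param pseudocount RPM pseudocount added before the log (default 1).
#' @param labels column-name suffixes, default \code{c("a","b")}.
#' @return data.frame with the consensus interval and \code{log2_rpm_<label>}
#'   columns.
#' @export
compare_signal <- function(fp_a, fp_b, pseudocount = 1,
                           labels = c("a", "b")) {
  both <- rbind(as.data.frame(fp_a)[, c("chrom", "start", "end", "strand")],
                as.data.frame(fp_b)[, c("chrom", "start", "end", "strand")])
  if (nrow(both) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  cons <- granges_to_bed(GenomicRanges::reduce(as_granges(both),
                                               ignore.strand = FALSE))
  rpm_in <- function(fp) {
    out <- numeric(nrow(cons))
    if (nrow(fp) == 0) return(out)
    h <- overlap_pairs(cons, as.data.frame(fp))
    s <- tapply(fp$rpm[h$subject], h$query, sum)
    out[as.integer(names(s))] <- as.vector(s)
    out
  }
  cons[[paste0("log2_rpm_", labels[1])]] <- log2(rpm_in(fp_a) + pseudocount)
  cons[[paste0("log2_rpm_", labels[2])]] <- log2(rpm_in(fp_b) + pseudocount)
  cons <- cons[order(cons$chrom, cons$start, cons$strand), , drop = FALSE]
  rownames(cons) <- NULL
  cons
}

#' Write footprints as BED6
#'
#' Name is \code{gene_id|category} when available, score the larger replicate
#' read count.
#' @param footprints a \code{footprints} frame.
#' @param path output path.
#' @export
write_footprints_bed <- function(footprints, path) {
  df <- as.data.frame(footprints)
  df$name <- if (!is.null(df$gene_id))
    paste(ifelse(is.na(df$gene_id), ".", df$gene_id),
          if (!is.null(df$category)) df$category else ".", sep = "|")
  else "."
  df$score <- pmax(df$count_rep1, df$count_rep2)
  write_bed(df, path)
}
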