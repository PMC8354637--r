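#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: target genes
#' carry 5'UTRs drawn log-normally around a median of 93 nt at 42% GC,
#' background genes around 69 nt at 39% GC; planted 5'UTR-proximal binding
#' sites are enriched 4-fold over an INPUT mean of 15 reads per cluster, with
#' negative-binomial count noise, across two replicates of four sample types
#' (WT, C130Y, dRRM, IgG) x (CLIP, INPUT).
#'
#' @param seed integer seed; expanded into per-stage substreams (genome =
#'   seed, counts = seed + 1) so stages can be regenerated independently.
#' @param n_genes total genes on the single simulated chromosome.
#' @param n_target_genes genes carrying a planted footprint (first
#'   \code{n_target_genes} of the shuffled gene order).
#' @param target_utr_median,background_utr_median log-normal medians (nt).
#' @param utr_sdlog log-normal sdlog shared by both groups.
#' @param target_gc,background_gc per-base GC probability of 5'UTRs.
#' @param enrichment CLIP/INPUT mean fold enrichment of planted sites.
#' @param input_mean mean INPUT read count per cluster window.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param expression_sdlog log-normal sdlog of the per-locus expression
#'   factor (median 1) shared by all libraries at a locus; models the spread
#'   of transcript abundance that makes replicate cluster intensities
#'   correlate, as seen between biological replicates of the assay.
#' @param library_size total mapped reads per library.
#' @param background_rate probability that a non-target gene carries a sticky
#'   background site (enriched in all samples, removed by background
#'   subtraction).
#' @param control_signal_frac CLIP signal at planted sites in the dRRM/IgG
#'   controls, as a fraction of \code{input_mean} (residual background only).
#' @param sl_fraction fraction of genes annotated as trans-spliced (about 70
#'   percent of C. elegans mRNAs).
#' @param intron_prob probability that a gene's CDS contains one intron.
#' @param read_length simulated read length (nt).
#' @param gene_gap intergenic gap (nt).
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1, n_genes = 500, n_target_genes = 150,
                              target_utr_median = 93,
                              background_utr_median = 69,
                              utr_sdlog = 0.6,
                              target_gc = 0.42, background_gc = 0.39,
                              enrichment = 4, input_mean = 15,
                              dispersion = 0.1, expression_sdlog = 0.5,
                              library_size = 2e6,
                              background_rate = 0.2,
                              control_signal_frac = 0.2,
                              sl_fraction = 0.7, intron_prob = 0.3,
                              read_length = 30, gene_gap = 200) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$n_target_genes >= 0,
            cfg$n_target_genes <= cfg$n_genes,
            cfg$target_utr_median > 0, cfg$background_utr_median > 0,
            cfg$target_gc >= 0, cfg$target_gc <= 1,
            cfg$background_gc >= 0, cfg$background_gc <= 1,
            cfg$background_rate >= 0, cfg$background_rate <= 1,
            cfg$sl_fraction >= 0, cfg$sl_fraction <= 1,
            cfg$dispersion >= 0, cfg$library_size >= 1)
  class(cfg) <- "simulation_config"
  cfg
}

rand_seq <- function(n, gc, other_gc = NULL) {
  if (n == 0) return("")
  p <- c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rand_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a single-chromosome genome with known 5'UTR structure
#'
#' Each gene has an intergenic gap, a 5'UTR of sampled length and GC, a CDS
#' (optionally split by one intron), and a 3'UTR; strands are random. Target
#' genes carry a planted 5'UTR-proximal footprint interval spanning the
#' 3'-most (up to) 40 nt of the 5'UTR and the first 20 nt of the CDS. A
#' configurable fraction of genes receives a trans-splice (SL) annotation.
#' Deterministic under a fixed seed.
#'
#' @param config a \code{simulation_config}.
#' @return list of class \code{simulated_genome}: \code{annotation}
#'   (a \code{genome_annotation}), \code{sequences}
#'   (\code{Biostrings::DNAStringSet}), \code{trans_splice} (data.frame),
#'   \code{truth} (list with \code{footprints} interval frame and
#'   \code{genes} table), \code{config}.
#' @export
simulate_genome <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  target <- c(rep(TRUE, config$n_target_genes),
              rep(FALSE, n - config$n_target_genes))
  gene_ids <- sprintf("g%04d", seq_len(n))

  chrom <- "chrS"
  pieces <- character(0)
  offset <- 0
  transcripts <- list()
  truth_fp <- list()
  gene_rows <- list()

  for (i in seq_len(n)) {
    gid <- gene_ids[i]
    txid <- paste0(gid, ".t1")
    strand <- sample(c("+", "-"), 1)
    gc <- if (target[i]) config$target_gc else config$background_gc
    med <- if (target[i]) config$target_utr_median else config$background_utr_median
    L5 <- max(1, round(stats::rlnorm(1, meanlog = log(med),
                                     sdlog = config$utr_sdlog)))
    n_codons <- sample(100:300, 1)
    L3 <- sample(50:200, 1)
    cds_seq <- rand_cds(n_codons)
    Lc <- nchar(cds_seq)
    utr5_seq <- rand_seq(L5, gc)
    utr3_seq <- rand_seq(L3, 0.36)

    has_intron <- stats::runif(1) < config$intron_prob
    if (has_intron) {
      Li <- sample(50:150, 1)
      cut <- 3 * sample(15:40, 1)  # codon boundary, >= 45 nt into the CDS
      intron_seq <- paste0("GT", rand_seq(Li - 4, 0.3), "AG")
      tx_seq <- paste0(utr5_seq, substr(cds_seq, 1, cut), intron_seq,
                       substr(cds_seq, cut + 1, Lc), utr3_seq)
      ## transcript-forward segment layout [start, end)
      segs <- list(utr5 = c(0, L5),
                   cds1 = c(L5, L5 + cut),
                   intron = c(L5 + cut, L5 + cut + Li),
                   cds2 = c(L5 + cut + Li, L5 + cut + Li + (Lc - cut)),
                   utr3 = c(L5 + Lc + Li, L5 + Lc + Li + L3))
    } else {
      tx_seq <- paste0(utr5_seq, cds_seq, utr3_seq)
      segs <- list(utr5 = c(0, L5), cds1 = c(L5, L5 + Lc),
                   utr3 = c(L5 + Lc, L5 + Lc + L3))
    }
    totlen <- nchar(tx_seq)

    gap_seq <- rand_seq(config$gene_gap, 0.36)
    gene_off <- offset + config$gene_gap
    block <- if (strand == "+") tx_seq else revcomp_chr(tx_seq)
    pieces <- c(pieces, gap_seq, block)
    offset <- gene_off + totlen

    ## transcript-forward [a, b) -> genomic [start, end)
    to_genomic <- function(seg) {
      if (strand == "+") c(gene_off + seg[1], gene_off + seg[2])
      else c(gene_off + totlen - seg[2], gene_off + totlen - seg[1])
    }
    gseg <- lapply(segs, to_genomic)
    mk <- function(names) {
      x <- do.call(rbind, lapply(gseg[names], function(g)
        data.frame(chrom = chrom, start = g[1], end = g[2], strand = strand)))
      x <- x[order(x$start), , drop = FALSE]
      rownames(x) <- NULL
      x
    }
    cds_names <- intersect(c("cds1", "cds2"), names(segs))
    cds_iv <- mk(cds_names)
    utr5_iv <- mk("utr5")
    utr3_iv <- mk("utr3")
    ## exons = everything but the intron, merged where contiguous
    exon_src <- rbind(utr5_iv, cds_iv, utr3_iv)
    exon_src <- exon_src[order(exon_src$start), , drop = FALSE]
    exons <- exon_src[1, , drop = FALSE]
    for (k in seq_len(nrow(exon_src))[-1]) {
      if (exon_src$start[k] == exons$end[nrow(exons)])
        exons$end[nrow(exons)] <- exon_src$end[k]
      else exons <- rbind(exons, exon_src[k, ])
    }
    rownames(exons) <- NULL

    cmin <- min(cds_iv$start); cmax <- max(cds_iv$end)
    transcripts[[txid]] <- list(
      gene_id = gid, transcript_id = txid, chrom = chrom, strand = strand,
      exons = exons, cds = cds_iv, utr5 = utr5_iv, utr3 = utr3_iv,
      start_codon_pos = if (strand == "+") cmin else cmax - 1,
      stop_codon_pos = if (strand == "+") cmax - 3 else cmin + 2)

    if (target[i]) {
      u <- min(40, L5)
      fp_tx <- c(L5 - u, L5 + 20)  # transcript-forward, inside exon 1
      g <- to_genomic(fp_tx)
      truth_fp[[gid]] <- data.frame(chrom = chrom, start = g[1], end = g[2],
                                    strand = strand, gene_id = gid)
    }
    gene_rows[[gid]] <- data.frame(gene_id = gid, target = target[i],
                                   utr5_length = L5, utr5_gc = gc,
                                   strand = strand)
  }

  genome <- Biostrings::DNAStringSet(paste(c(pieces,
                                             rand_seq(config$gene_gap, 0.36)),
                                           collapse = ""))
  names(genome) <- chrom

  annotation <- structure(
    list(transcripts = transcripts,
         genes = lapply(split(names(transcripts),
                              vapply(transcripts, `[[`, character(1),
                                     "gene_id")), unname)),
    class = "genome_annotation")

  sl <- stats::runif(n) < config$sl_fraction
  trans_splice <- data.frame(
    gene_id = gene_ids[sl],
    transcript_id = paste0(gene_ids[sl], ".t1"),
    sl_type = sample(c("SL1", "SL2"), sum(sl), replace = TRUE,
                     prob = c(0.8, 0.2)),
    mature_utr_length = vapply(gene_ids[sl], function(g)
      gene_rows[[g]]$utr5_length, numeric(1)))
  rownames(trans_splice) <- NULL

  fp <- do.call(rbind, truth_fp)
  if (is.null(fp))
    fp <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), strand = character(0),
                     gene_id = character(0))
  rownames(fp) <- NULL
  structure(list(annotation = annotation, sequences = genome,
                 trans_splice = trans_splice,
                 truth = list(footprints = fp,
                              genes = do.call(rbind, gene_rows)),
                 config = config),
            class = "simulated_genome")
}

#' @export
print.simulated_genome <- function(x, ...) {
  cat("simulated_genome:", length(x$annotation$transcripts), "genes,",
      nrow(x$truth$footprints), "planted footprints, chromosome of",
      sum(Biostrings::width(x$sequences)), "bp\n")
  invisible(x)
}

#' Write simulated genome files (FASTA + GFF3 + trans-splice TSV)
#'
#' @param sim a \code{simulated_genome}.
#' @param dir output directory (created if needed).
#' @return invisible named vector of paths.
#' @export
write_simulated_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  sl <- file.path(dir, "trans_splice.tsv")
  Biostrings::writeXStringSet(sim$sequences, fa)

  rows <- list()
  for (tx in sim$annotation$transcripts) {
    span <- c(min(tx$exons$start), max(tx$exons$end))
    rows[[length(rows) + 1]] <- data.frame(
      type = c("gene", "mRNA"), start = span[1], end = span[2],
      strand = tx$strand, ID = c(tx$gene_id, tx$transcript_id),
      Parent = c(NA, tx$gene_id))
    part <- function(df, type) {
      if (nrow(df) == 0) return(NULL)
      data.frame(type = type, start = df$start, end = df$end,
                 strand = df$strand, ID = NA, Parent = tx$transcript_id)
    }
    rows[[length(rows) + 1]] <- do.call(rbind, list(
      part(tx$exons, "exon"), part(tx$cds, "CDS"),
      part(tx$utr5, "five_prime_UTR"), part(tx$utr3, "three_prime_UTR")))
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = names(sim$sequences)[1],
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- ifelse(is.na(tab$Parent), NA_character_, tab$Parent)
  ## every CDS piece starts on a codon boundary in this generator
  gr$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff, format = "gff3")

  utils::write.table(sim$trans_splice, sl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, trans_splice = sl))
}

#' Simulate seCLIP read libraries with planted enrichment
#'
#' Generates (WT, C130Y, dRRM, IgG) x (CLIP, INPUT) x 2 replicates. Planted
#' footprint windows receive CLIP counts with mean \code{enrichment x
#' input_mean} in WT and C130Y and residual signal
#' (\code{control_signal_frac x input_mean}) in the dRRM/IgG controls; sticky
#' background windows (placed on non-target genes at the configured rate) are
#' enriched in every sample, so they are called everywhere and removed by
#' background subtraction. Counts are negative-binomial; reads of fixed
#' length tile each window at evenly spaced starts so overlap-merging
#' recovers the window exactly.
#'
#' @param sim a \code{simulated_genome}.
#' @param config a \code{simulation_config} (defaults to the one inside
#'   \code{sim}).
#' @return list of class \code{simulated_clip}: \code{libraries} (nested list
#'   \code{[[sample]][[assay]][[replicate]]} of \code{sample_library}) and
#'   \code{loci} (interval frame with \code{gene_id} and \code{type} =
#'   planted/background).
#' @export
simulate_clip <- function(sim, config = sim$config) {
  set.seed(config$seed + 1L)
  if (config$enrichment <= 1 && nrow(sim$truth$footprints) > 0)
    warning("enrichment <= 1: planted footprints will rarely pass thresholds")

  planted <- sim$truth$footprints
  planted$type <- rep("planted", nrow(planted))

  genes <- sim$truth$genes
  bg_genes <- genes$gene_id[!genes$target &
                              stats::runif(nrow(genes)) < config$background_rate]
  bg <- do.call(rbind, lapply(bg_genes, function(gid) {
    tx <- sim$annotation$transcripts[[paste0(gid, ".t1")]]
    L5 <- utr5_length(tx)
    u <- min(40, L5)
    ## same UTR-proximal zone as planted sites, transcript-forward [L5-u, L5+20)
    a <- L5 - u; b <- L5 + 20
    ex1 <- if (tx$strand == "+") min(tx$exons$start) else max(tx$exons$end)
    if (tx$strand == "+")
      data.frame(chrom = tx$chrom, start = ex1 + a, end = ex1 + b,
                 strand = tx$strand, gene_id = gid, type = "background")
    else
      data.frame(chrom = tx$chrom, start = ex1 - b, end = ex1 - a,
                 strand = tx$strand, gene_id = gid, type = "background")
  }))
  loci <- rbind(planted, bg)
  rownames(loci) <- NULL

  samples <- c("WT", "C130Y", "dRRM", "IgG")
  ## per-locus expression factor, shared by every sample and replicate:
  ## transcript abundance varies across loci, count noise does not
  expr <- stats::rlnorm(nrow(loci), meanlog = 0,
                        sdlog = config$expression_sdlog)
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  draw <- function(mu) {
    if (is.infinite(size)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = size, mu = mu)
  }
  tile_reads <- function(counts) {
    keep <- which(counts >= 1)
    if (length(keep) == 0)
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0)))
    do.call(rbind, lapply(keep, function(j) {
      k <- counts[j]
      w <- loci$end[j] - loci$start[j]
      rl <- min(config$read_length, w)
      starts <- if (k == 1) loci$start[j] else
        round(seq(loci$start[j], loci$end[j] - rl, length.out = k))
      data.frame(chrom = loci$chrom[j], start = starts, end = starts + rl,
                 strand = loci$strand[j])
    }))
  }

  libraries <- list()
  for (s in samples) {
    libraries[[s]] <- list(CLIP = list(), INPUT = list())
    for (r in 1:2) {
      clip_mu <- ifelse(loci$type == "background",
                        config$enrichment * config$input_mean,
                        if (s %in% c("WT", "C130Y"))
                          config$enrichment * config$input_mean
                        else config$control_signal_frac * config$input_mean)
      clip_counts <- draw(clip_mu * expr)
      input_counts <- draw(config$input_mean * expr)
      libraries[[s]]$CLIP[[r]] <- sample_library(
        paste0(s, "_CLIP"), r, tile_reads(clip_counts), config$library_size)
      libraries[[s]]$INPUT[[r]] <- sample_library(
        paste0(s, "_INPUT"), r, tile_reads(input_counts), config$library_size)
    }
  }
  structure(list(libraries = libraries, loci = loci, config = config),
            class = "simulated_clip")
}

#' Recall and precision of called footprints against planted truth
#'
#' Matching is by >= 1 bp same-strand overlap.
#'
#' @param called a \code{footprints} frame.
#' @param truth interval frame of planted footprints.
#' @return list: \code{recall} (planted sites overlapped by a call),
#'   \code{precision} (calls overlapping a planted site), \code{n_called},
#'   \code{n_truth}.
#' @export
footprint_recovery <- function(called, truth) {
  called <- as.data.frame(called)
  if (nrow(truth) == 0)
    return(list(recall = NA_real_,
                precision = if (nrow(called)) 0 else NA_real_,
                n_called = nrow(called), n_truth = 0L))
  hits <- overlap_pairs(truth, called)
  list(recall = length(unique(hits$query)) / nrow(truth),
       precision = if (nrow(called) == 0) NA_real_ else
         length(unique(hits$subject)) / nrow(called),
       n_called = nrow(called), n_truth = nrow(truth))
}

#' Simulate a polysome-gradient absorbance trace from Gaussian peaks
#'
#' Absorbance is \code{baseline + sum of Gaussian peaks (+ optional noise)};
#' the analytic area of each named region is computed from the Gaussian CDF,
#' so Simpson's-rule integration can be checked against closed-form truth.
#'
#' @param peaks data.frame with columns \code{center}, \code{amplitude},
#'   \code{width} (Gaussian sigma); may have zero rows.
#' @param span two numbers: trace position range.
#' @param step sampling step (> 0).
#' @param baseline constant AU offset.
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed RNG seed for the noise stream.
#' @param regions named list of region ranges, as in [absorbance_trace()].
#' @return list: \code{trace} (an \code{absorbance_trace} with the baseline
#'   preset) and \code{truth_areas} (named analytic areas per region).
#' @export
simulate_polysome_trace <- function(peaks, span = c(0, 10), step = 0.01,
                                    baseline = 0, noise_sd = 0, seed = 1,
                                    regions = list()) {
  if (step <= 0) stop("step must be > 0")
  peaks <- as.data.frame(peaks)
  x <- seq(span[1], span[2], by = step)
  y <- rep(baseline, length(x))
  for (j in seq_len(nrow(peaks)))
    y <- y + peaks$amplitude[j] *
      exp(-(x - peaks$center[j])^2 / (2 * peaks$width[j]^2))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(x), sd = noise_sd)
  }
  truth <- vapply(regions, function(r) {
    if (nrow(peaks) == 0) return(0)
    sum(peaks$amplitude * peaks$width * sqrt(2 * pi) *
          (stats::pnorm(r[2], peaks$center, peaks$width) -
             stats::pnorm(r[1], peaks$center, peaks$width)))
  }, numeric(1))
  list(trace = absorbance_trace(x, y, regions = regions, baseline = baseline),
       truth_areas = truth)
}
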