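# Shared fixtures and independent brute-force oracles.
# The oracles use naive loops only (no package internals, no IRanges), so the
# vectorised implementations are checked against a literal reading of the
# retention and subtraction rules.

make_lib <- function(reads, size = 1e6, sample = "X", replicate = 1) {
  sample_library(sample, replicate, reads, size)
}

# n identical reads covering [start, end) on one strand
stack_reads <- function(n, chrom, start, end, strand) {
  if (n == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  data.frame(chrom = chrom, start = rep(start, n), end = rep(end, n),
             strand = strand)
}

# naive interval merge; merges overlapping or book-ended (gap <= min_gap)
# same-chrom same-strand intervals; count = number merged
oracle_merge <- function(df, min_gap = 0) {
  if (nrow(df) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      count = numeric(0)))
  df <- df[order(df$chrom, df$strand, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!is.null(cur) && row$chrom == cur$chrom && row$strand == cur$strand &&
        row$start <= cur$end + min_gap) {
      cur$end <- max(cur$end, row$end)
      cur$count <- cur$count + 1
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- data.frame(chrom = row$chrom, start = row$start, end = row$end,
                        strand = row$strand, count = 1)
    }
  }
  out[[length(out) + 1]] <- cur
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

overlaps1 <- function(a, b) {
  a$chrom == b$chrom & a$strand == b$strand & a$start < b$end & b$start < a$end
}

# literal sentence-level footprint filter:
# merge reads per replicate into clusters; union overlapping/book-ended
# clusters across replicates into consensus windows; a window is a footprint
# iff it holds >= 1 read in both replicates and, in at least one replicate
# (or both, per scope), >= min_reads reads with >= min_fc RPM enrichment
# over the INPUT reads counted in the same window.
oracle_call_footprints <- function(clip, input, cfg) {
  cl1 <- oracle_merge(clip[[1]]$reads)
  cl2 <- oracle_merge(clip[[2]]$reads)
  cons <- oracle_merge(rbind(cl1[, 1:4], cl2[, 1:4]), min_gap = 0)
  n_over <- function(win, reads) {
    k <- 0
    for (j in seq_len(nrow(reads)))
      if (overlaps1(win, reads[j, ])) k <- k + 1
    k
  }
  keep <- list()
  for (i in seq_len(nrow(cons))) {
    win <- cons[i, ]
    c1 <- n_over(win, clip[[1]]$reads)
    c2 <- n_over(win, clip[[2]]$reads)
    if (!(c1 >= 1 && c2 >= 1)) next
    r1 <- c1 / clip[[1]]$total_mapped_reads * 1e6
    r2 <- c2 / clip[[2]]$total_mapped_reads * 1e6
    i1 <- n_over(win, input[[1]]$reads) / input[[1]]$total_mapped_reads * 1e6
    i2 <- n_over(win, input[[2]]$reads) / input[[2]]$total_mapped_reads * 1e6
    f1 <- (r1 + cfg$pseudocount) / (i1 + cfg$pseudocount)
    f2 <- (r2 + cfg$pseudocount) / (i2 + cfg$pseudocount)
    p1 <- c1 >= cfg$min_reads && f1 >= cfg$min_fc
    p2 <- c2 >= cfg$min_reads && f2 >= cfg$min_fc
    ok <- if (cfg$threshold_scope == "either_replicate") p1 || p2 else p1 && p2
    if (ok)
      keep[[length(keep) + 1]] <-
        data.frame(chrom = win$chrom, start = win$start, end = win$end,
                   strand = win$strand, count_rep1 = c1, count_rep2 = c2)
  }
  if (length(keep) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      count_rep1 = numeric(0), count_rep2 = numeric(0)))
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

oracle_subtract <- function(fp, bgs) {
  keep <- rep(TRUE, nrow(fp))
  for (i in seq_len(nrow(fp)))
    for (bg in bgs)
      for (j in seq_len(nrow(bg)))
        if (overlaps1(fp[i, ], bg[j, ])) keep[i] <- FALSE
  fp[keep, , drop = FALSE]
}

# random CLIP/INPUT fixture: loci with tiled reads, Poisson-ish counts
random_clip_fixture <- function(seed, n_loci = 40) {
  set.seed(seed)
  loci <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_loci, replace = TRUE),
    start = sample(0:5000, n_loci, replace = TRUE),
    strand = sample(c("+", "-"), n_loci, replace = TRUE))
  loci$end <- loci$start + sample(30:80, n_loci, replace = TRUE)
  tile <- function(counts, read_len = 20) {
    pieces <- lapply(which(counts > 0), function(j) {
      k <- counts[j]
      s <- if (k == 1) loci$start[j] else
        round(seq(loci$start[j], loci$end[j] - read_len, length.out = k))
      data.frame(chrom = loci$chrom[j], start = s, end = s + read_len,
                 strand = loci$strand[j])
    })
    if (length(pieces) == 0)
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0)))
    do.call(rbind, pieces)
  }
  clip <- lapply(1:2, function(r)
    make_lib(tile(rpois(n_loci, sample(5:35, 1))), 1e6, "T_CLIP", r))
  input <- lapply(1:2, function(r)
    make_lib(tile(rpois(n_loci, 10)), 1e6, "T_INPUT", r))
  list(clip = clip, input = input)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free samples only)
oracle_mw_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); m <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  combs <- utils::combn(n, m)
  us <- apply(combs, 2, function(idx) u_of(all_v[idx], all_v[-idx]))
  u_lo <- min(u_obs, m * (n - m) - u_obs)
  2 * mean(us <= u_lo)
}

# tiny hand-built GFF3 annotation (see test-genome_model for the expected
# geometry); written to a temp file once per session
toy_gff3_path <- local({
  p <- NULL
  function() {
    if (!is.null(p) && file.exists(p)) return(p)
    lines <- c(
      "##gff-version 3",
      # gA (+): 2 exons, CDS only -> UTRs derived from geometry
      "chr1\ttoy\tgene\t101\t400\t.\t+\t.\tID=gA",
      "chr1\ttoy\tmRNA\t101\t400\t.\t+\t.\tID=gA.t1;Parent=gA",
      "chr1\ttoy\texon\t101\t200\t.\t+\t.\tParent=gA.t1",
      "chr1\ttoy\texon\t301\t400\t.\t+\t.\tParent=gA.t1",
      "chr1\ttoy\tCDS\t151\t200\t.\t+\t0\tParent=gA.t1",
      "chr1\ttoy\tCDS\t301\t380\t.\t+\t0\tParent=gA.t1",
      # gB (+): explicit five_prime_UTR feature
      "chr1\ttoy\tgene\t501\t700\t.\t+\t.\tID=gB",
      "chr1\ttoy\tmRNA\t501\t700\t.\t+\t.\tID=gB.t1;Parent=gB",
      "chr1\ttoy\texon\t501\t700\t.\t+\t.\tParent=gB.t1",
      "chr1\ttoy\tfive_prime_UTR\t501\t520\t.\t+\t.\tParent=gB.t1",
      "chr1\ttoy\tCDS\t521\t700\t.\t+\t0\tParent=gB.t1",
      # gC (-): CDS at the left end, so the 5'UTR lies to its right
      "chr1\ttoy\tgene\t1001\t1100\t.\t-\t.\tID=gC",
      "chr1\ttoy\tmRNA\t1001\t1100\t.\t-\t.\tID=gC.t1;Parent=gC",
      "chr1\ttoy\texon\t1001\t1100\t.\t-\t.\tParent=gC.t1",
      "chr1\ttoy\tCDS\t1001\t1050\t.\t-\t0\tParent=gC.t1")
    p <<- tempfile(fileext = ".gff3")
    writeLines(lines, p)
    p
  }
})
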