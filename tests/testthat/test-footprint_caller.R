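# helper: one locus per scenario, CLIP/INPUT libraries with stacked reads.
# library size 1e6 so RPM values equal raw counts.
scenario_libs <- function(clip1, clip2, in1, in2, start = 0, end = 100) {
  mk <- function(n, s, r) make_lib(stack_reads(n, "chr1", start, end, "+"),
                                   1e6, s, r)
  list(clip = list(mk(clip1, "S_CLIP", 1), mk(clip2, "S_CLIP", 2)),
       input = list(mk(in1, "S_INPUT", 1), mk(in2, "S_INPUT", 2)))
}

test_that("thresholds in one replicate suffice when present in both", {
  ## rep1: 25 reads, FC (25+1)/(12+1) = 2; rep2: 5 reads, FC (5+1)/(5+1) = 1
  l <- scenario_libs(25, 5, 12, 5)
  fp <- call_footprints(l$clip, l$input)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$passing_replicate, "1")
  expect_equal(fp$count_rep1, 25)
  expect_equal(fp$fc_rep1, 2)
})

test_that("a cluster present in only one replicate is rejected", {
  l <- scenario_libs(100, 0, 5, 5)  # 100 reads, FC huge, but rep2 empty
  fp <- call_footprints(l$clip, l$input)
  expect_equal(nrow(fp), 0)
})

test_that("the 20-read and 1.5-fold thresholds are inclusive", {
  ## both reps 19 reads at FC 10 -> rejected
  l19 <- scenario_libs(19, 19, 1, 1)
  expect_equal(nrow(call_footprints(l19$clip, l19$input)), 0)
  ## both reps 20 reads at FC exactly 1.5: (20+1)/(13+1) = 1.5 -> retained
  l20 <- scenario_libs(20, 20, 13, 13)
  fp <- call_footprints(l20$clip, l20$input)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$fc_rep1, 1.5)
  expect_equal(fp$passing_replicate, "both")
  ## FC just below threshold -> rejected: (20+1)/(14+1) = 1.4
  l14 <- scenario_libs(20, 20, 14, 14)
  expect_equal(nrow(call_footprints(l14$clip, l14$input)), 0)
})

test_that("threshold_scope = both_replicates demands thresholds in each", {
  l <- scenario_libs(25, 5, 12, 5)  # passes in rep1 only
  strict <- footprint_config(threshold_scope = "both_replicates")
  expect_equal(nrow(call_footprints(l$clip, l$input, strict)), 0)
  expect_equal(nrow(call_footprints(l$clip, l$input)), 1)
})

test_that("enrichment fold change follows its formula", {
  expect_equal(enrichment_fc(30, 20, 1e-9), 1.5, tolerance = 1e-8)
  expect_equal(enrichment_fc(7, 7, 0.5), 1.0)   # identity for any pseudocount
  expect_equal(enrichment_fc(10, 0, 1), 11.0)
  expect_error(enrichment_fc(-1, 0, 1), ">= 0")
  expect_error(enrichment_fc(1, 1, 0), "> 0")
})

test_that("call_footprints equals the literal brute-force filter", {
  cfg <- footprint_config()
  for (seed in 101:105) {
    fx <- random_clip_fixture(seed)
    got <- call_footprints(fx$clip, fx$input, cfg)
    want <- oracle_call_footprints(fx$clip, fx$input, cfg)
    expect_equal(as.data.frame(got)[, names(want)], want)
  }
})

test_that("raising thresholds never adds footprints", {
  fx <- random_clip_fixture(7)
  base <- call_footprints(fx$clip, fx$input, footprint_config())
  key <- function(fp) paste(fp$chrom, fp$start, fp$end, fp$strand)
  for (cfg in list(footprint_config(min_reads = 30),
                   footprint_config(min_fc = 2.5),
                   footprint_config(min_reads = 25, min_fc = 2))) {
    stricter <- call_footprints(fx$clip, fx$input, cfg)
    expect_true(all(key(stricter) %in% key(base)))
  }
})

test_that("background subtraction removes any >=1 bp same-strand overlap", {
  fp <- data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300),
                   strand = "+", rpm = 1)
  bg1 <- data.frame(chrom = "chr1", start = 99, end = 150, strand = "+")
  expect_equal(subtract_background(fp, bg1)$start, 200)  # 1 bp overlap removed
  bg_other_strand <- data.frame(chrom = "chr1", start = 0, end = 300,
                                strand = "-")
  expect_equal(nrow(subtract_background(fp, bg_other_strand)), 2)
  expect_equal(subtract_background(fp), fp)  # no background set: identity
  empty_bg <- fp[0, ]
  expect_equal(subtract_background(fp, empty_bg), fp)
})

test_that("subtraction is idempotent, anti-monotone, and matches brute force", {
  set.seed(9)
  rand_iv <- function(n) {
    s <- sample(0:2000, n, replace = TRUE)
    data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = s, end = s + sample(20:80, n, replace = TRUE),
               strand = sample(c("+", "-"), n, replace = TRUE))
  }
  for (i in 1:5) {
    fp <- rand_iv(40); bg1 <- rand_iv(15); bg2 <- rand_iv(15)
    got <- subtract_background(fp, bg1, bg2)
    expect_equal(got, oracle_subtract(fp, list(bg1, bg2)),
                 ignore_attr = TRUE)
    ## idempotent
    expect_equal(subtract_background(got, bg1, bg2), got)
    ## anti-monotone: more background never keeps more footprints
    expect_lte(nrow(got), nrow(subtract_background(fp, bg1)))
  }
})

test_that("target gene counting merges overlapping footprints across samples", {
  fp3 <- data.frame(chrom = "chr1", start = c(0, 200, 400, 600),
                    end = c(100, 300, 500, 700), strand = "+",
                    gene_id = c("g1", "g1", "g1", "g2"),
                    category = "five_prime_proximal")
  out <- count_target_genes(fp3)
  expect_equal(out$n_footprints, 4)
  expect_equal(out$n_genes, 2)
  ## identical WT and C130Y footprint -> one merged interval, one gene
  wt <- data.frame(chrom = "chr1", start = 0, end = 100, strand = "+",
                   gene_id = "g1", category = "five_prime_proximal")
  out2 <- count_target_genes(wt, wt)
  expect_equal(out2$n_footprints, 1)
  expect_equal(out2$n_genes, 1)
})

test_that("target gene counting matches a brute-force set union", {
  set.seed(21)
  n <- 200
  s <- sample(0:20000, n, replace = TRUE)
  fp <- data.frame(chrom = "chr1", start = s,
                   end = s + sample(30:70, n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   gene_id = sample(sprintf("g%02d", 1:60), n, replace = TRUE),
                   category = "five_prime_proximal")
  half <- seq_len(n / 2)
  out <- count_target_genes(fp[half, ], fp[-half, ])
  merged <- oracle_merge(fp[, c("chrom", "start", "end", "strand")])
  expect_equal(out$n_footprints, nrow(merged))
  expect_equal(out$n_genes, length(unique(fp$gene_id)))
})

test_that("signal comparison matches footprints by overlap", {
  wt <- data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300),
                   strand = "+", rpm = c(8, 2))
  same <- compare_signal(wt, wt)
  expect_equal(same$log2_rpm_a, same$log2_rpm_b)
  only_wt <- compare_signal(wt, wt[0, ], pseudocount = 1)
  expect_equal(only_wt$log2_rpm_b, rep(log2(1), 2))  # absent -> log2(pc)
  expect_equal(only_wt$log2_rpm_a, log2(c(8, 2) + 1))
})
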