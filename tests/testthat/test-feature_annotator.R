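# toy annotation for category tests, built from GFF3 text:
# gA (+): exon [100,200)+[300,400), CDS [150,200)+[300,380)
#   -> utr5 [100,150), intron [200,300), utr3 [380,400)
# gB (+): exon [500,700), utr5 [500,520), CDS [520,700)
# gC (-): exon [1000,1100), CDS [1000,1050) -> utr5 [1050,1100)
toy_ann <- function() load_annotation(toy_gff3_path())

fp1 <- function(start, end, strand = "+", rpm = 1)
  data.frame(chrom = "chr1", start = start, end = end, strand = strand,
             rpm = rpm)

test_that("category precedence implements the 5'UTR-proximal grouping", {
  ann <- toy_ann()
  lab <- function(fp) annotate_footprints(fp, ann)$category
  expect_equal(lab(fp1(110, 140)), "five_prime_proximal")   # inside 5'UTR
  ## deep inside the CDS, far from the UTR: still grouped as proximal
  expect_equal(lab(fp1(330, 360)), "five_prime_proximal")
  expect_equal(lab(fp1(385, 395)), "three_prime_utr")       # past stop codon
  expect_equal(lab(fp1(220, 280)), "intron")
  expect_equal(lab(fp1(2000, 2100)), "intergenic")
  ## 5'UTR/CDS beats 3'UTR when a footprint touches both
  expect_equal(lab(fp1(370, 390)), "five_prime_proximal")
  ## gene assignment goes with the winning overlap
  got <- annotate_footprints(fp1(110, 140), ann)
  expect_equal(got$gene_id, "gA")
  got_c <- annotate_footprints(fp1(1060, 1090, strand = "-"), ann)
  expect_equal(got_c$category, "five_prime_proximal")
  expect_equal(got_c$gene_id, "gC")
})

test_that("non-coding transcripts get their own category", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tncRNA\t101\t200\t.\t+\t.\tID=nc.t1;Parent=ncg",
               "chr1\ttoy\texon\t101\t200\t.\t+\t.\tParent=nc.t1"), gff)
  ann <- load_annotation(gff)
  got <- annotate_footprints(fp1(120, 160), ann)
  expect_equal(got$category, "non_coding")
  expect_equal(got$gene_id, "ncg")
})

test_that("category proportions tally counts and sum to one", {
  fp <- data.frame(category = c(rep("five_prime_proximal", 3),
                                "three_prime_utr"))
  out <- category_proportions(fp)
  expect_equal(out$fraction[out$category == "five_prime_proximal"], 0.75)
  expect_equal(out$fraction[out$category == "three_prime_utr"], 0.25)
  expect_equal(category_proportions(fp[1, , drop = FALSE])$fraction, 1.0)
  expect_error(category_proportions(fp[0, , drop = FALSE]), "no footprints")
  set.seed(5)
  big <- data.frame(category = sample(c("five_prime_proximal",
                                        "three_prime_utr", "intron"),
                                      100, replace = TRUE))
  out <- category_proportions(big)
  expect_equal(sum(out$fraction), 1)
  expect_equal(out$count[match("intron", out$category)],
               sum(big$category == "intron"))
})

test_that("one footprint spreads its RPM over its in-window offsets", {
  ann <- toy_ann()
  ## gB start codon at 520; footprint [510,530) covers offsets -10..+9
  fp <- annotate_footprints(fp1(510, 530, rpm = 2), ann)
  prof <- metagene_coverage(fp, ann, "start", window = c(50, 50))
  expect_equal(sum(prof$coverage), 40)  # 20 offsets x RPM 2
  hit <- prof$offsets >= -10 & prof$offsets <= 9
  expect_true(all(prof$coverage[hit] == 2))
  expect_true(all(prof$coverage[!hit] == 0))
})

test_that("an empty footprint set yields an all-zero profile", {
  ann <- toy_ann()
  fp <- annotate_footprints(fp1(510, 530), ann)[0, ]
  prof <- metagene_coverage(fp, ann, "start")
  expect_true(all(prof$coverage == 0))
})

test_that("offsets are spliced distances: introns are excluded", {
  ann <- toy_ann()
  ## gA start codon at 150; footprint [190,310) spans the intron [200,300);
  ## exonic bases are 190..199 (offsets 40..49) and 300..309 (offsets 50..59)
  fp <- annotate_footprints(fp1(190, 310, rpm = 1), ann)
  prof <- metagene_coverage(fp, ann, "start", window = c(100, 100))
  expect_equal(sum(prof$coverage), 20)
  expect_true(all(prof$coverage[prof$offsets %in% 40:59] == 1))
  expect_true(all(prof$coverage[!prof$offsets %in% 40:59] == 0))
})

test_that("minus-strand offsets run 5' to 3' along the transcript", {
  ann <- toy_ann()
  ## gC (-): start codon at genomic 1049; genomic [1045,1055) covers
  ## transcript offsets -5..+4
  fp <- annotate_footprints(fp1(1045, 1055, strand = "-", rpm = 3), ann)
  prof <- metagene_coverage(fp, ann, "start", window = c(20, 20))
  hit <- prof$offsets >= -5 & prof$offsets <= 4
  expect_true(all(prof$coverage[hit] == 3))
  expect_true(all(prof$coverage[!hit] == 0))
})

test_that("stop-codon anchoring places 3'UTR footprints downstream", {
  ann <- toy_ann()
  ## gA stop codon first base at 377; 3'UTR footprint [385,395)
  fp <- annotate_footprints(fp1(385, 395, rpm = 1), ann)
  prof <- metagene_coverage(fp, ann, "stop", window = c(50, 100))
  ## genomic 385..394 are transcript offsets... 377 is tx offset 0;
  ## 380 -> +3 etc (intron-free in this region): offsets 8..17
  expect_true(all(prof$coverage[prof$offsets %in% 8:17] == 1))
  expect_equal(sum(prof$coverage), 10)
})

test_that("overlapping footprints add per-offset and match brute force", {
  ann <- toy_ann()
  fp <- rbind(fp1(510, 530, rpm = 2), fp1(520, 540, rpm = 5))
  fp <- annotate_footprints(fp, ann)
  w <- c(60, 60)
  prof <- metagene_coverage(fp, ann, "start", window = w)
  ## brute force: per-base loop over each footprint
  want <- numeric(sum(w) + 1)
  for (i in 1:2) {
    for (g in fp$start[i]:(fp$end[i] - 1)) {
      off <- g - 520          # single-exon plus-strand gene: offset is direct
      if (off >= -w[1] && off <= w[2])
        want[off + w[1] + 1] <- want[off + w[1] + 1] + fp$rpm[i]
    }
  }
  expect_equal(prof$coverage, want)
  ## conservation: profile sum = sum over footprints of rpm x covered offsets
  expect_equal(sum(prof$coverage), 2 * 20 + 5 * 20)
})

test_that("footprints on genes without the anchor are skipped with warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tncRNA\t101\t200\t.\t+\t.\tID=nc.t1;Parent=ncg",
               "chr1\ttoy\texon\t101\t200\t.\t+\t.\tParent=nc.t1"), gff)
  ann <- load_annotation(gff)
  fp <- annotate_footprints(fp1(120, 160), ann)
  expect_warning(prof <- metagene_coverage(fp, ann, "start"), "codon")
  expect_true(all(prof$coverage == 0))
})
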