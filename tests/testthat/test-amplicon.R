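test_that("primer-pair evidence classifies allele structure", {
  cls <- function(p1, p2, p3)
    classify_allele_from_primers(c(pair1 = p1, pair2 = p2, pair3 = p3))
  expect_equal(cls(TRUE, FALSE, FALSE), "WT_or_conversion")
  expect_equal(cls(FALSE, TRUE, FALSE), "CNL")
  expect_equal(cls(TRUE, FALSE, TRUE), "CNG")
  expect_equal(cls(TRUE, TRUE, FALSE), "MIXED")
  expect_error(cls(FALSE, FALSE, TRUE), "inconsistent")
  expect_error(cls(FALSE, FALSE, FALSE), "no amplification")
})

test_that("sentinel calls bracket the fusion breakpoint", {
  r <- locate_cnl_breakpoint(c("GENE", "GENE", "GENE", "PSEUDO", "PSEUDO",
                               "PSEUDO"))
  expect_equal(r$interval, c(3L, 4L))
  expect_false(r$non_canonical)

  r2 <- locate_cnl_breakpoint(c("GENE", "GENE", "NOCALL", "PSEUDO",
                                "PSEUDO"))
  expect_equal(r2$interval, c(2L, 4L))
  expect_false(r2$non_canonical)

  r3 <- locate_cnl_breakpoint(c("GENE", "PSEUDO", "GENE", "PSEUDO"))
  expect_true(r3$non_canonical)
  expect_equal(length(r3$transitions), 3L)

  expect_error(locate_cnl_breakpoint(rep("GENE", 4)), "no PSEUDO")
  expect_error(locate_cnl_breakpoint(rep("PSEUDO", 4)), "wrong amplicon")

  ## property: with error-free sentinel calls from a known breakpoint the
  ## interval always contains it
  set.seed(401)
  pos <- sort(sample(1000:9000, 12))
  for (i in 1:50) {
    bp <- runif(1, min(pos) + 1, max(pos) - 1)
    status <- ifelse(pos < bp, "GENE", "PSEUDO")
    if (all(status == "GENE") || all(status == "PSEUDO")) next
    r <- locate_cnl_breakpoint(status, site_ids = pos)
    expect_true(r$interval[1] < bp && bp < r$interval[2])
  }
})

test_that("homopolymer depth anomalies are flagged by run MAD statistics", {
  an <- data.frame(sample = c(5L, 11L), position = c(2L, 4L),
                   factor = c(0.5, 1.5))
  run <- simulate_run_depths(24, n_positions = 6, anomaly = an, seed = 17)
  flags <- detect_homopolymer_variants(run)
  expect_equal(flags[5, 2], "DELETION")
  expect_equal(flags[11, 4], "SNV")
  expect_equal(sum(flags != "NONE"), 2L)

  ## oracle: compute the flagged sample's robust z directly
  a <- run$pos_depth / run$flank_depth
  others <- a[-5, 2]
  z <- (a[5, 2] - median(others)) / mad(others)
  expect_lt(z, -5)

  ## MAD of zero falls back to a relative threshold with a warning
  flat <- list(pos_depth = matrix(c(100, 100, 100, 60), 4, 1),
               flank_depth = matrix(100, 4, 1))
  expect_warning(f2 <- detect_homopolymer_variants(flat), "relative")
  expect_equal(f2[4, 1], "DELETION")
  expect_equal(f2[1, 1], "NONE")
})

test_that("GQ filtering keeps records at or above threshold", {
  rec <- data.frame(id = 1:3, gq = c(651, 650, 649))
  out <- filter_variants_by_gq(rec)
  expect_equal(out$id, c(1L, 2L))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(nrow(filter_variants_by_gq(rec[0, ])), 0L)
  expect_warning(out2 <- filter_variants_by_gq(data.frame(id = 1)),
                 "no GQ")
  expect_equal(nrow(out2), 1L)
})

test_that("GQ filtering reads Clair-style VCF records", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t155235252\t.\tA\tG\t900\t.\t.\tGT:GQ\t0/1:900",
    "chr1\t155235727\t.\tC\tG\t300\t.\t.\tGT:GQ\t0/1:300"), vcf)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  out <- filter_variants_by_gq(v)
  expect_equal(nrow(out), 1L)
  expect_equal(out$POS, "155235252")
  expect_equal(attr(out, "n_removed"), 1L)
})
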