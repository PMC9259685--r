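test_that("binned depth reflects simulated coverage and CNV state", {
  ref <- fx_ref()
  reads <- fx_reads("wt_cons", seed = 5, error_rate = 0)
  prof <- extract_depth(reads, ref$model, ref$sequence)
  b <- prof$bins
  expect_lt(abs(mean(b$raw_depth) - 30) / 30, 0.05)
  expect_lt(median(abs(b$raw_depth - 30) / 30), 0.15)
  expect_true(all(b$gc_fraction >= 0 & b$gc_fraction <= 1))

  ## a fusion deletion halves unique-region depth relative to baseline
  cnl <- fx_sample("cnl_cov", h2 = list(allele_cnl(15850L)), seed = 6)
  pc <- extract_depth(load_reads(cnl$bam), ref$model, ref$sequence)
  ratio <- mean(pc$bins$raw_depth[pc$bins$region == "unique"]) /
    mean(pc$bins$raw_depth[pc$bins$region == "baseline"])
  expect_lt(abs(ratio - 0.5), 0.05)

  expect_error(extract_depth(reads[0, ], ref$model, ref$sequence),
               "degenerate")
})

test_that("GC correction is a no-op without bias and removes linear bias", {
  ref <- fx_ref()
  prof <- extract_depth(fx_reads("wt_cons", seed = 5, error_rate = 0),
                        ref$model, ref$sequence)
  corr <- gc_correct(prof)
  rel <- abs(corr$bins$raw_depth - prof$bins$raw_depth) /
    prof$bins$raw_depth
  expect_lt(max(rel), 0.02)

  biased <- fx_sample("gc_biased", seed = 13, gc_bias = -0.5,
                      error_rate = 0)
  pb <- extract_depth(load_reads(biased$bam), ref$model, ref$sequence)
  fit_raw <- coef(lm(raw_depth ~ gc_fraction, pb$bins))[2]
  pbc <- gc_correct(pb)
  fit_corr <- coef(lm(raw_depth ~ gc_fraction, pbc$bins))[2]
  ## slope in depth units per +10% GC, relative to mean depth
  slope10 <- function(s) abs(s) * 0.10 / mean(pb$bins$raw_depth)
  expect_gt(slope10(fit_raw), 0.1)   # the planted bias is visible
  expect_lt(slope10(fit_corr), 0.05) # and removed by correction

  ## degenerate single-stratum baseline: skipped with a warning
  one <- prof
  one$bins$gc_fraction <- 0.5
  expect_warning(g1 <- gc_correct(one), "skipped")
  expect_true(g1$gc_skipped)
  expect_equal(g1$bins$raw_depth, one$bins$raw_depth)
})

test_that("normalization is exact on synthetic profiles and gains", {
  mkprof <- function(u, b) {
    bins <- data.frame(
      start = seq_len(length(u) + length(b)), end = 2,
      raw_depth = c(u, b), gc_fraction = 0.5,
      region = rep(c("unique", "baseline"), c(length(u), length(b))))
    structure(list(bins = bins, corrected = TRUE, gc_skipped = FALSE),
              class = "depth_profile")
  }
  expect_equal(normalize_depth(mkprof(rep(30, 40), rep(30, 40)))$d, 2)
  expect_equal(normalize_depth(mkprof(rep(45, 40), rep(30, 40)))$d, 3)
  expect_error(normalize_depth(mkprof(rep(1, 40), rep(0, 40))), "zero")

  cng <- fx_sample("cng3_cov", h2 = list(allele_cng(15000L, 3L)), seed = 8)
  nd <- normalize_depth(gc_correct(extract_depth(
    load_reads(cng$bam), fx_ref()$model, fx_ref()$sequence)))
  expect_gt(nd$d, 4.6)
  expect_lt(nd$d, 5.4)
})

test_that("mixture CN calls match brute-force posterior enumeration", {
  expect_equal(call_total_cn(2.0)$cn_unique, 2L)
  expect_equal(call_total_cn(2.0)$cnv_class, "NONE")
  expect_equal(call_total_cn(1.02)$cn_unique, 1L)
  expect_equal(call_total_cn(1.02)$cnv_class, "CNL")

  ## independent oracle: explicit density evaluation over components 0..10
  oracle <- function(d, sigma0 = 0.12) {
    k <- 0:10
    dens <- dnorm(d, k, sigma0 * sqrt(pmax(k, 1)))
    list(cn = k[which.max(dens)], post = max(dens) / sum(dens))
  }
  got <- call_total_cn(4.93)
  exp_ <- oracle(4.93)
  expect_equal(got$cn_unique, 5L)
  expect_equal(got$cn_unique, exp_$cn)
  expect_equal(got$posterior, exp_$post, tolerance = 1e-12)
  expect_equal(got$cnv_class, "CNG")

  ## grid property: within 0.3 of an integer the MAP is that integer,
  ## and the MAP is non-decreasing in d
  d <- seq(0, 10, by = 0.01)
  calls <- vapply(d, function(x) call_total_cn(x)$cn_unique, 0L)
  near <- abs(d - round(d)) <= 0.3 & round(d) <= 8
  expect_true(all(calls[near] == round(d)[near]))
  expect_true(all(diff(calls) >= 0L))

  ## low posterior yields a no-call, never an error
  nc <- call_total_cn(2.5)
  expect_true(nc$no_call)
})
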