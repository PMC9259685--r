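test_that("mini reference is deterministic and hits identity targets", {
  r1 <- build_mini_reference(7)
  r2 <- build_mini_reference(7)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$model$sites, r2$model$sites)
  expect_false(identical(build_mini_reference(8)$sequence, r1$sequence))

  expect_lt(abs(r1$identity_overall - 0.96), 0.003)
  expect_lt(abs(r1$identity_homology - 0.98), 0.003)
  expect_error(build_mini_reference(1, identity_overall = 0.5),
               "identity")

  ## phasing inter-site gaps match the stated spacing range
  ph <- r1$model$sites[r1$model$sites$in_phasing_set, ]
  expect_true(all(diff(ph$gene_pos) >= 14 & diff(ph$gene_pos) <= 315))
})

test_that("reference FASTA round-trips through Biostrings", {
  f <- tempfile(fileext = ".fa")
  write_reference_fasta(fx_ref(), f)
  x <- Biostrings::readDNAStringSet(f)
  expect_equal(as.character(x[[1]]), fx_ref()$sequence)
  expect_true(file.exists(paste0(f, ".fai")))
})

test_that("simulated read volume matches the requested depth", {
  sim <- fx_sample("wt_cons", seed = 5, error_rate = 0)
  reads <- load_reads(sim$bam)
  total_bases <- sum(reads$rwidth)
  glen <- nchar(fx_ref()$sequence)
  expect_lt(abs(total_bases / glen - 30) / 30, 0.02)
})

test_that("allele specifications determine the truth record", {
  ref <- fx_ref()
  t1 <- paralogcnv:::sample_truth(ref, list(list(), list()))
  expect_equal(t1$cn_unique, 2L)
  expect_equal(t1$cnv_class, "NONE")

  t2 <- paralogcnv:::sample_truth(
    ref, list(list(), list(allele_cng(15000L, 3L))))
  expect_equal(t2$cn_unique, 5L)
  expect_equal(t2$cnv_class, "CNG")

  t3 <- paralogcnv:::sample_truth(
    ref, list(list(), list(allele_cnl(16600L))))
  expect_equal(t3$cn_unique, 1L)
  expect_false(t3$breakpoints[[1]]$pathogenic)
  t4 <- paralogcnv:::sample_truth(
    ref, list(list(), list(allele_cnl(15850L))))
  expect_true(t4$breakpoints[[1]]$pathogenic)
  expect_equal(t4$variants[[1]]$label, "RecNciI")
})

test_that("run depth simulation plants the requested anomalies", {
  an <- data.frame(sample = c(3L, 7L), position = c(2L, 5L),
                   factor = c(0.5, 1.5))
  run <- simulate_run_depths(24, n_positions = 6, anomaly = an, seed = 9)
  expect_equal(dim(run$pos_depth), c(24L, 6L))
  expect_equal(run$truth$expected, c("DELETION", "SNV"))
  null_run <- simulate_run_depths(12, n_positions = 4, seed = 9)
  expect_equal(nrow(null_run$truth), 0L)
  expect_error(simulate_run_depths(2, seed = 1), ">= 3")
})
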