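test_that("site CN estimates match brute-force binomial enumeration", {
  expect_equal(estimate_site_cn(12, 12, 4L)$cn_gene, 2L)
  expect_equal(estimate_site_cn(0, 25, 2L)$cn_gene, 0L)
  expect_true(is.na(estimate_site_cn(4, 3, 2L)$cn_gene))  # depth < 10

  ## oracle: enumerate the four binomial likelihoods for cn_total 3
  k <- 20; n <- 30
  lik <- sapply(0:3, function(c_)
    dbinom(k, n, min(max(c_ / 3, 0.01), 0.99)))
  got <- estimate_site_cn(20, 10, 3L)
  expect_equal(got$cn_gene, (0:3)[which.max(lik)])
  expect_equal(got$cn_gene, 2L)
  expect_equal(got$posterior, max(lik) / sum(lik), tolerance = 1e-12)
})

test_that("pooled counts are balanced in wild type and alignment-invariant", {
  ref <- fx_ref()
  counts <- count_site_bases(fx_reads("wt_counts", seed = 21), ref$model)
  cov <- counts[counts$covered & counts$k_gene + counts$k_pseudo >= 20, ]
  expect_gt(nrow(cov), 300)
  pvals <- mapply(function(a, b) binom.test(a, a + b)$p.value,
                  cov$k_gene, cov$k_pseudo)
  expect_lt(mean(pvals < 0.001), 0.01)
  expect_equal(sum(cov$k_other) / sum(cov$k_gene + cov$k_pseudo), 0,
               tolerance = 0.01)

  ## pooling makes counts invariant to the paralog the read aligned to:
  ## the same gene-base reads at the gene and at the pseudogene position
  ## give identical SiteCounts
  s <- ref$model$sites[40, ]
  seq_g <- substring(ref$sequence, s$gene_pos - 49, s$gene_pos + 50)
  at_gene <- make_reads(paste0("r", 1:5), rep(s$gene_pos - 50L, 5), seq_g)
  at_pseudo <- make_reads(paste0("r", 1:5), rep(s$pseudo_pos - 50L, 5),
                          seq_g, mapq = 0L)
  cg <- count_site_bases(at_gene, ref$model)
  cp <- count_site_bases(at_pseudo, ref$model)
  expect_equal(cg$k_gene[40], 5L)
  expect_equal(cp$k_gene[40], 5L)
  expect_identical(cg[, c("k_gene", "k_pseudo", "k_other")],
                   cp[, c("k_gene", "k_pseudo", "k_other")])

  ## a third base counts as other
  seq_x <- seq_g
  substr(seq_x, 51, 51) <- setdiff(c("A", "C", "G", "T"),
                                   c(s$gene_base, s$pseudo_base))[1]
  cx <- count_site_bases(make_reads("rx", s$gene_pos - 50L, seq_x),
                         ref$model)
  expect_equal(cx$k_other[40], 1L)
  expect_equal(cx$k_gene[40], 0L)
})

test_that("changepoint detection localizes CNL, CNG and conversions", {
  mkcounts <- function(kv, nv) data.frame(
    site_id = seq_along(kv), k_gene = kv, k_pseudo = nv - kv,
    k_other = 0L, covered = TRUE)

  ## CNL: [2,2,2,1,1] at cn_total 3 -> one breakpoint in (site 3, site 4)
  s3 <- site_cn_series(mkcounts(c(27, 27, 27, 13, 13), rep(40, 5)), 3L)
  expect_equal(s3$cn_gene, c(2L, 2L, 2L, 1L, 1L))
  bp <- detect_cn_transitions(s3, "CNL")
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$kind, "CNL")
  expect_equal(c(bp$left_site, bp$right_site), c(3L, 4L))

  ## CNG: step up at cn_total 5
  s5 <- site_cn_series(mkcounts(c(48, 48, 72, 72), rep(120, 4)), 5L)
  bg <- detect_cn_transitions(s5, "CNG")
  expect_equal(bg$kind, "CNG")
  expect_equal(c(bg$left_site, bg$right_site), c(2L, 3L))

  ## conversion: [2,2,1,1,2] at diploid cn_total 4 brackets sites 3-4
  s4 <- site_cn_series(mkcounts(c(60, 60, 30, 30, 60), rep(120, 5)), 4L)
  cv <- detect_cn_transitions(s4, "NONE")
  expect_equal(cv$kind, c("CONVERSION_START", "CONVERSION_END"))
  expect_equal(cv$left_site[1], 2L)
  expect_equal(cv$right_site[1], 3L)
  expect_equal(cv$left_site[2], 4L)
  expect_equal(cv$right_site[2], 5L)

  ## constant series -> nothing
  sc <- site_cn_series(mkcounts(rep(60, 6), rep(120, 6)), 4L)
  expect_equal(nrow(detect_cn_transitions(sc, "NONE")), 0L)
})

test_that("CNL pathogenicity follows coding-region intersection", {
  m <- fx_ref()$model
  mk <- function(l, r) data.frame(kind = "CNL", left_site = 1L,
                                  right_site = 2L, cn_before = 2L,
                                  cn_after = 1L, left_pos = l,
                                  right_pos = r)
  ce <- m$coding_region$end
  ## interval entirely 3' of the coding region: UTR-only fusion
  expect_false(classify_cnl_pathogenicity(mk(ce + 10L, ce + 200L),
                                          m)$pathogenic)
  ## interval inside the coding region
  inside <- classify_cnl_pathogenicity(mk(ce - 500L, ce - 300L), m)
  expect_true(inside$pathogenic)
  expect_false(inside$boundary)
  ## interval straddling the coding 3' boundary: conservative, flagged
  strad <- classify_cnl_pathogenicity(mk(ce - 50L, ce + 50L), m)
  expect_true(strad$pathogenic)
  expect_true(strad$boundary)
})

test_that("simulated breakpoint intervals contain the truth", {
  ref <- fx_ref()
  for (i in 1:4) {
    bp_true <- c(15820L, 16000L, 16600L, 15100L)[i]
    sim <- fx_sample(paste0("bp", i), h2 = list(allele_cnl(bp_true)),
                     seed = 100 + i)
    reads <- load_reads(sim$bam)
    counts <- count_site_bases(reads, ref$model)
    series <- site_cn_series(counts, 3L, ref$model)
    bp <- detect_cn_transitions(series, "CNL", ref$model)
    expect_equal(nrow(bp), 1L)
    expect_true(bp$left_pos < bp_true && bp_true <= bp$right_pos,
                label = paste("breakpoint", bp_true, "in interval"))
  }
})
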