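test_that("fragments are built from pooled positions with mate merging", {
  ref <- fx_ref()
  ## a RecNciI-conversion carrier yields fragments linking gene bases to
  ## the converted pseudogene bases
  ids <- phasing_ids()
  sim <- fx_sample("recn_frag",
                   h2 = list(allele_conversion(ids[8], ids[10])),
                   seed = 31)
  fr <- extract_fragments(sim$bam, ref$model)
  mat <- unclass(fr)
  p_at_recn <- rowSums(mat[, 8:10, drop = FALSE] == "P", na.rm = TRUE)
  g_link <- rowSums(mat[, 1:7, drop = FALSE] == "G", na.rm = TRUE)
  expect_gt(sum(p_at_recn >= 1 & g_link >= 1), 0)
  expect_gt(sum(p_at_recn >= 2), 0)

  ## mates disagreeing at a site drop that site from the fragment
  ph <- ref$model$sites[ref$model$sites$in_phasing_set, ][1, ]
  base_at <- function(b) {
    s <- substring(ref$sequence, ph$gene_pos - 19, ph$gene_pos + 20)
    substr(s, 21, 21) <- b
    s
  }
  reads <- make_reads(c("fr1", "fr1"), rep(ph$gene_pos - 20L, 2),
                      c(base_at(ph$gene_base), base_at(ph$pseudo_base)))
  fr2 <- extract_fragments(reads, ref$model)
  expect_equal(nrow(unclass(fr2)), 0L)
})

test_that("assembly recovers canonical, variant and decoy haplotypes", {
  ref <- fx_ref()
  S <- 10L
  ## pure canonical fragments
  fr <- make_fragments(c(strrep("G", S), strrep("P", S)), c(20, 20))
  haps <- assemble_haplotypes(fr, ref$model, max_haplotypes = 4)
  expect_setequal(haps$allele_string, c(strrep("G", S), strrep("P", S)))

  ## a simulated heterozygous p.L483P carrier: the variant haplotype is
  ## assembled distinct from both canonicals
  sim <- fx_sample("l483p_hap", h2 = list(allele_snv("p.L483P")),
                   seed = 33)
  frs <- extract_fragments(sim$bam, ref$model)
  h <- assemble_haplotypes(frs, ref$model, max_haplotypes = 4)
  h <- call_haplotype_cn(h, frs, 4L)
  expect_true("GGGGGGGPGG" %in% h$allele_string)
  expect_equal(sum(h$cn), 4L)

  ## reverse-converted pseudogene decoys are assembled as distinct
  ## pseudogene-origin hybrids, not merged into the gene wild type
  ids <- phasing_ids()
  dec <- fx_sample("decoy_hap", h1 = list(allele_reverse_snv(ids[8])),
                   h2 = list(allele_reverse_indel()), seed = 35)
  rep <- call_sample(dec$bam, ref$model, ref$sequence)
  gene_side <- paralogcnv:::hap_is_gene_origin(rep$haplotypes$allele_string,
                                               rep$haplotypes$imputed)
  hybrids <- rep$haplotypes$allele_string[gene_side == FALSE]
  expect_true(any(grepl("G", hybrids)))  # decoys carry gene bases
  expect_equal(nrow(rep$calls), 0L)      # but never produce variant calls
  expect_equal(rep$scenario$genotype, "WT")
})

test_that("haplotype copy numbers maximize the composition likelihood", {
  ref <- fx_ref()
  S <- 10L
  wt <- strrep("G", S); ps <- strrep("P", S)
  fr <- make_fragments(c(wt, ps), c(48, 52))
  h <- assemble_haplotypes(fr, ref$model, max_haplotypes = 4)
  h <- call_haplotype_cn(h, fr, 4L)
  expect_equal(h$cn[match(c(wt, ps), h$allele_string)], c(2L, 2L))

  ## brute-force oracle over all compositions of 4 into 3 positive parts
  v <- "GGGGGGGPGG"
  fr3 <- make_fragments(c(wt, v, ps), c(30, 30, 60))
  h3 <- assemble_haplotypes(fr3, ref$model, max_haplotypes = 4)
  h3 <- call_haplotype_cn(h3, fr3, 4L)
  counts <- c(30, 30, 60)
  comps <- list(c(1, 1, 2), c(1, 2, 1), c(2, 1, 1))
  ll <- vapply(comps, function(cc) dmultinom(counts, prob = cc / 4,
                                             log = TRUE), 0)
  best <- comps[[which.max(ll)]]
  got <- h3$cn[match(c(wt, v, ps), h3$allele_string)]
  expect_equal(got, as.integer(best))
  expect_equal(got, c(1L, 1L, 2L))

  ## a single haplotype takes all copies
  h1 <- call_haplotype_cn(
    data.frame(allele_string = wt, support = 10L,
               imputed = strrep(".", S), stringsAsFactors = FALSE),
    make_fragments(wt, 10), 4L)
  expect_equal(h1$cn, 4L)
})

test_that("scenario comparison separates WT, HET, HOM and compound het", {
  ref <- fx_ref()
  S <- 10L
  wt <- strrep("G", S); ps <- strrep("P", S); v <- "GGGGGGGPGG"
  d448 <- "GGGGGGPGGG"

  run_sc <- function(haps, counts, cn_total) {
    fr <- make_fragments(haps, counts)
    h <- assemble_haplotypes(fr, ref$model, max_haplotypes = cn_total)
    h <- call_haplotype_cn(h, fr, cn_total)
    compare_scenarios(h, fr, cn_total)
  }
  expect_equal(run_sc(c(wt, ps), c(50, 50), 4L)$genotype, "WT")
  sc_het <- run_sc(c(wt, v, ps), c(25, 25, 50), 4L)
  expect_equal(sc_het$genotype, "HET")
  expect_equal(sc_het$wildtype_gba_copies, 1L)
  sc_cmp <- run_sc(c(v, d448, ps), c(25, 25, 50), 4L)
  expect_equal(sc_cmp$genotype, "COMPOUND_HET")
  expect_equal(sc_cmp$wildtype_gba_copies, 0L)
  sc_hom <- run_sc(c(v, ps), c(50, 50), 4L)
  expect_equal(sc_hom$genotype, "HOM")
})

test_that("recombinant classification maps P-site sets and mechanisms", {
  ref <- fx_ref()
  m <- ref$model
  S <- 10L
  mkhaps <- function(strings, cns) data.frame(
    allele_string = strings, support = 20L, imputed = strrep(".", S),
    cn = cns, stringsAsFactors = FALSE)
  no_bp <- data.frame(kind = character(), left_site = integer(),
                      right_site = integer(), cn_before = integer(),
                      cn_after = integer(), left_pos = integer(),
                      right_pos = integer())
  sc_het <- structure(list(wildtype_gba_copies = 1L,
                           log_likelihood_ratio = 5, genotype = "HET",
                           no_call = FALSE), class = "scenario_call")
  cn_none <- call_total_cn(2.0)
  cn_cnl <- call_total_cn(1.0)

  ## P at exactly the RecNciI sites, no CNV -> RecNciI conversion
  recn <- "GGGGGGGPPP"
  out <- classify_recombinant(sc_het, mkhaps(c(strrep("G", S), recn,
                                               strrep("P", S)),
                                             c(1L, 1L, 2L)),
                              no_bp, cn_none, m)
  expect_equal(out$label, "RecNciI")
  expect_equal(out$mechanism, "CONVERSION")

  ## same haplotype with CNL and a 5' breakpoint -> pathogenic fusion
  ph <- m$sites[m$sites$in_phasing_set, ]
  bp <- data.frame(kind = "CNL", left_site = ph$site_id[7],
                   right_site = ph$site_id[8], cn_before = 2L,
                   cn_after = 1L, left_pos = ph$gene_pos[7],
                   right_pos = ph$gene_pos[8])
  out2 <- classify_recombinant(sc_het, mkhaps(c(strrep("G", S), recn,
                                                strrep("P", S)),
                                              c(1L, 1L, 1L)),
                               bp, cn_cnl, m)
  expect_setequal(out2$label, c("CNL", "RecNciI"))
  expect_equal(out2$mechanism[out2$label == "RecNciI"], "CNL")
  expect_true(all(out2$pathogenic))

  ## c.1263del+RecTL with no CN change -> gene conversion
  del_rectl <- "GGGGGPPPPP"
  out3 <- classify_recombinant(sc_het, mkhaps(c(strrep("G", S), del_rectl,
                                                strrep("P", S)),
                                              c(1L, 1L, 2L)),
                               no_bp, cn_none, m)
  expect_equal(out3$label, "c.1263del+RecTL")
  expect_equal(out3$mechanism, "CONVERSION")
})

test_that("haplotype copy numbers always sum to the combined CN", {
  ref <- fx_ref()
  for (nm in c("recn_frag", "l483p_hap")) {
    sim <- fx_sample(nm)
    rep <- call_sample(sim$bam, ref$model, ref$sequence)
    expect_equal(sum(rep$haplotypes$cn), rep$cn_call$cn_total)
  }
})
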