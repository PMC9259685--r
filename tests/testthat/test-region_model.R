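test_that("interval and model invariants are enforced with named errors", {
  expect_error(genomic_interval("c", 10, 10), "start must be <")
  expect_error(genomic_interval("", 0, 10), "contig")

  m <- fx_ref()$model
  expect_silent(validate_model(m))

  ## phasing flag outside the homology window violates the invariant
  bad <- m
  i <- which(!bad$sites$in_phasing_set)[1]
  bad$sites$in_phasing_set[i] <- TRUE
  expect_error(validate_model(bad), "phasing")

  ## a gbap1-like variant whose alt is not the pseudo base at that site
  bad2 <- m
  j <- which(bad2$variants$label == "p.L483P")
  bad2$variants$alt_allele[j] <- bad2$variants$ref_allele[j]
  expect_error(validate_model(bad2), "gbap1_like")

  ## unique region must not overlap a paralog
  bad3 <- m
  bad3$unique_cn_region <- genomic_interval(m$contig, m$gene$start + 10L,
                                            m$gene$start + 500L)
  expect_error(validate_model(bad3), "unique_cn_region")
})

test_that("model files round-trip byte-identically and validate on load", {
  m <- fx_ref()$model
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  save_model(m, f1)
  save_model(load_model(f1), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(load_model(tempfile()), "not found")
  broken <- tempfile(fileext = ".json")
  writeLines('{"contig": "x"}', broken)
  expect_error(load_model(broken), "missing keys")
})

test_that("bundled GBA model has 82 sites with the ten-site phasing set", {
  path <- system.file("extdata", "gba_hg38_model.json",
                      package = "paralogcnv")
  m <- load_model(path)
  expect_equal(nrow(m$sites), 82L)
  expect_equal(sum(m$sites$in_phasing_set), 10L)
  expect_setequal(names(m$recombinants),
                  c("p.L483P", "p.D448H", "c.1263del55", "RecNciI",
                    "RecTL", "c.1263del+RecTL"))
  expect_true(all(m$recombinants$RecNciI %in% m$recombinants$RecTL))
  expect_true(all(m$recombinants$RecTL %in%
                    m$recombinants[["c.1263del+RecTL"]]))
  ## hg38 pseudogene-error sites ship masked
  expect_equal(sum(!m$sites$reliable), 3L)
})

test_that("BED export writes 0-based half-open intervals", {
  f <- tempfile(fileext = ".bed")
  export_model_bed(fx_ref()$model, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2[bed$V4 == "gene"], fx_ref()$model$gene$start)
  expect_equal(bed$V3[bed$V4 == "gene"], fx_ref()$model$gene$end)
})

test_that("gene-to-pseudogene mapping anchors, interpolates and refuses", {
  m <- fx_ref()$model
  s <- m$sites
  ## anchor identity at every site
  for (k in c(1L, 10L, nrow(s) %/% 2L, nrow(s)))
    expect_equal(map_gene_to_pseudo(m, s$gene_pos[k]), s$pseudo_pos[k])

  ## linearity at the midpoint of an indel-free anchor pair
  k <- which(diff(s$gene_pos) == diff(s$pseudo_pos) &
               diff(s$gene_pos) %% 2L == 0L)[1]
  mid <- (s$gene_pos[k] + s$gene_pos[k + 1L]) %/% 2L
  expect_equal(map_gene_to_pseudo(m, mid),
               (s$pseudo_pos[k] + s$pseudo_pos[k + 1L]) %/% 2L)

  ## positions inside the 55 bp gene-only insertion have no homolog
  ins <- fx_ref()$insert
  expect_error(map_gene_to_pseudo(m, ins$start + 10L), "no-mapping")
  expect_error(map_gene_to_pseudo(m, m$gene$start - 100L), "no-mapping")

  ## strict monotonicity over a position grid
  grid <- seq(m$gene$start, m$gene$end - 1L, by = 97L)
  vals <- suppressWarnings(vapply(grid, function(p)
    tryCatch(map_gene_to_pseudo(m, p), error = function(e) NA_integer_),
    0L))
  expect_true(all(diff(vals[!is.na(vals)]) > 0L))
})
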