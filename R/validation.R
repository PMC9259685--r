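## End-to-end validation harness: simulate samples across the recombinant
## allele classes, run the full caller, and score recovery of the
## (CNV class, variant label, mechanism) triple and breakpoint intervals
## against simulator truth.

recovery_classes <- function() {
  c("WT", "L483P_het", "RecNciI_conversion", "RecNciI_CNL",
    "CNL_nonpathogenic", "CNG", "CNG_L483P", "del_RecTL_conversion",
    "compound_het")
}

## draw the allele specs (and truth-relevant parameters) for one class
draw_class_specs <- function(class, ref) {
  ph <- phasing_sites(ref$model)
  ins <- ref$insert
  rand_int <- function(lo, hi) lo + sample.int(hi - lo, 1L)
  cnl_bp_path <- function() rand_int(ph$gene_pos[7] + 1L,
                                     ph$gene_pos[8] - 1L)
  cnl_bp_nonpath <- function() rand_int(16550L, 16880L)
  cng_bp <- function() {
    repeat {
      bp <- rand_int(14850L, 16850L)
      if (bp < ins$start - 20L || bp >= ins$end + 20L) return(bp)
    }
  }
  switch(class,
    WT = list(h1 = list(), h2 = list()),
    L483P_het = list(h1 = list(), h2 = list(allele_snv("p.L483P"))),
    RecNciI_conversion = list(
      h1 = list(),
      h2 = list(allele_conversion(ph$site_id[8], ph$site_id[10]))),
    RecNciI_CNL = list(h1 = list(), h2 = list(allele_cnl(cnl_bp_path()))),
    CNL_nonpathogenic = list(h1 = list(),
                             h2 = list(allele_cnl(cnl_bp_nonpath()))),
    CNG = list(h1 = list(),
               h2 = list(allele_cng(cng_bp(), sample.int(6L, 1L)))),
    CNG_L483P = list(h1 = list(allele_snv("p.L483P")),
                     h2 = list(allele_cng(cng_bp(), sample.int(6L, 1L)))),
    del_RecTL_conversion = list(
      h1 = list(),
      h2 = list(allele_conversion(ph$site_id[6], ph$site_id[10]))),
    compound_het = list(h1 = list(allele_snv("p.L483P")),
                        h2 = list(allele_snv("p.D448H"))),
    stop("unknown class: ", class))
}

#' Score a sample report against simulator truth
#'
#' @param report a `sample_report` from [call_sample()].
#' @param truth the truth record from [simulate_sample()].
#' @return list: `cnv_match`, `variants_match` (labels + mechanisms),
#'   `triple_match` (all of the above), `bp_contained` (breakpoint interval
#'   contains the true breakpoint; NA when the truth has none),
#'   `false_variant` (any variant label not in the truth).
#' @export
score_recovery <- function(report, truth) {
  cnv_match <- report$cn_call$cnv_class == truth$cnv_class &&
    report$cn_call$cn_unique == truth$cn_unique
  truth_v <- truth$variants
  tlab <- vapply(truth_v, `[[`, "", "label")
  tmech <- vapply(truth_v, `[[`, "", "mechanism")
  calls <- report$calls
  vcalls <- calls[!calls$label %in% c("CNL", "CNG"), , drop = FALSE]
  variants_match <- setequal(vcalls$label, tlab) &&
    all(vapply(seq_along(tlab), function(i)
      any(vcalls$label == tlab[i] & vcalls$mechanism == tmech[i]), TRUE))
  ## pathogenicity of CNL must agree
  path_match <- TRUE
  tbp <- truth$breakpoints
  if (length(tbp)) {
    for (b in tbp) {
      if (b$kind != "CNL") next
      got <- calls[calls$label == "CNL", , drop = FALSE]
      path_match <- path_match && nrow(got) > 0L &&
        identical(got$pathogenic[1], b$pathogenic)
    }
  }
  bp_contained <- NA
  if (length(tbp)) {
    bp_contained <- all(vapply(tbp, function(b) {
      rows <- report$breakpoints[report$breakpoints$kind == b$kind, ,
                                 drop = FALSE]
      nrow(rows) > 0L && any(rows$left_pos < b$gene_pos &
                               b$gene_pos <= rows$right_pos)
    }, TRUE))
  }
  false_variant <- length(setdiff(vcalls$label, tlab)) > 0L
  list(cnv_match = cnv_match, variants_match = variants_match,
       path_match = path_match,
       triple_match = cnv_match && variants_match && path_match,
       bp_contained = bp_contained, false_variant = false_variant)
}

#' Run the end-to-end genotype-recovery suite
#'
#' Simulates `n_per_class` samples for each recombinant allele class at the
#' configured depth, runs the full caller on each, and scores recovery.
#'
#' @param ref a [build_mini_reference()] object.
#' @param n_per_class samples per class.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param depth mean coverage (default 30).
#' @param classes subset of classes (default: all).
#' @param dir scratch directory for BAMs (default temporary).
#' @return data.frame with one row per sample: `class`, `seed`,
#'   `cnv_match`, `variants_match`, `triple_match`, `bp_contained`,
#'   `false_variant`.
#' @export
run_recovery_suite <- function(ref, n_per_class, seed, depth = 30,
                               classes = recovery_classes(),
                               dir = tempfile("recovery")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(class = classes, rep = seq_len(n_per_class),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cls <- grid$class[i]
    sseed <- (seed * 7919L + i * 104729L) %% 2000000000L
    specs <- with_seed(sseed, draw_class_specs(cls, ref))
    sim <- simulate_sample(ref, specs$h1, specs$h2,
                           sim_config(depth = depth, seed = sseed),
                           dir = dir, sample_id = sprintf("r%05d", i))
    report <- call_sample(sim$bam, ref$model, ref$sequence,
                          sample_id = sim$sample_id)
    sc <- score_recovery(report, sim$truth)
    unlink(c(sim$bam, paste0(sim$bam, ".bai"),
             file.path(dir, paste0(sim$sample_id, ".truth.json"))))
    out[[i]] <- data.frame(class = cls, seed = sseed,
                           cnv_match = sc$cnv_match,
                           variants_match = sc$variants_match,
                           triple_match = sc$triple_match,
                           bp_contained = sc$bp_contained,
                           false_variant = sc$false_variant)
  }
  do.call(rbind, out)
}
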