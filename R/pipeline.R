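#' @keywords internal
"_PACKAGE"

#' Call CNVs, recombinants and known variants for one sample
#'
#' Runs the full short-read pipeline: depth extraction, GC correction and
#' normalization in the unique inter-paralog region, mixture-model copy
#' number, per-site gene CN with breakpoint detection, phasing of the
#' exon 9-11 sites with the wild-type-copy scenario comparison, recombinant
#' classification, and targeted genotyping of the non-homology variants.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param model a [paralog_model()].
#' @param ref_seq reference sequence (character scalar or FASTA path).
#' @param bin_size depth bin width (default 200).
#' @param sigma0 mixture component SD at diploid scale (default 0.12).
#' @param posterior_threshold CN no-call threshold (default 0.95).
#' @param min_hap_support minimum fragments per haplotype (default 3).
#' @param sample_id sample name for the report.
#' @return A `sample_report`: list with `sample_id`, `cn_call`, `series`,
#'   `breakpoints`, `haplotypes`, `scenario`, `calls` (recombinant/CNV
#'   entries), `targeted` (known-variant genotypes), `warnings`.
#' @export
call_sample <- function(bam, model, ref_seq, bin_size = 200L,
                        sigma0 = 0.12, posterior_threshold = 0.95,
                        min_hap_support = 3L, sample_id = "sample") {
  warnings <- character(0)
  reads <- load_reads(bam)
  profile <- extract_depth(reads, model, ref_seq, bin_size)
  profile <- withCallingHandlers(gc_correct(profile), warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  nd <- normalize_depth(profile)
  cn_call <- call_total_cn(nd, sigma0 = sigma0,
                           posterior_threshold = posterior_threshold)
  if (cn_call$no_call)
    warnings <- c(warnings, sprintf(
      "copy number no-call (posterior %.3f at d=%.2f)", cn_call$posterior,
      cn_call$d))

  counts <- count_site_bases(reads, model)
  series <- site_cn_series(counts, cn_call$cn_total, model)
  breakpoints <- detect_cn_transitions(series, cn_call$cnv_class, model)
  if (any(breakpoints$kind == "UNRESOLVED"))
    warnings <- c(warnings, "site-CN pattern inconsistent with CNV class")

  fragments <- extract_fragments(reads, model)
  haplotypes <- assemble_haplotypes(fragments, model,
                                    max_haplotypes = cn_call$cn_total,
                                    min_hap_support = min_hap_support)
  scenario <- NULL
  if (nrow(haplotypes)) {
    if (cn_call$cnv_class == "CNG")
      haplotypes <- split_hybrid_chimeras(haplotypes, fragments,
                                          cn_call$cn_total)
    haplotypes <- call_haplotype_cn(haplotypes, fragments,
                                    cn_call$cn_total)
    haplotypes <- reconcile_haplotypes(haplotypes, fragments, series,
                                       model, cn_call$cn_total)
    breakpoints <- refine_breakpoints(breakpoints, haplotypes, cn_call,
                                      model)
    scenario <- compare_scenarios(haplotypes, fragments, cn_call$cn_total)
    if (isTRUE(scenario$no_call))
      warnings <- c(warnings, "scenario comparison inconclusive")
  } else {
    scenario <- structure(list(wildtype_gba_copies = NA_integer_,
                               log_likelihood_ratio = NA_real_,
                               genotype = NA_character_, no_call = TRUE),
                          class = "scenario_call")
    warnings <- c(warnings, "no phasing fragments recovered")
  }
  calls <- classify_recombinant(scenario, haplotypes, breakpoints,
                                cn_call, model)
  targeted <- call_known_variants(reads, model)

  structure(list(sample_id = sample_id, cn_call = cn_call,
                 series = series, breakpoints = breakpoints,
                 haplotypes = haplotypes, scenario = scenario,
                 calls = calls, targeted = targeted,
                 warnings = warnings),
            class = "sample_report")
}

#' Write a sample report as JSON
#'
#' @param report a `sample_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  x <- list(sample_id = report$sample_id,
            cn = unclass(report$cn_call),
            scenario = unclass(report$scenario),
            breakpoints = report$breakpoints,
            haplotypes = report$haplotypes,
            calls = report$calls,
            targeted = report$targeted,
            warnings = report$warnings)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a sample report as TSV (one row per call)
#'
#' @param report a `sample_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
report_to_tsv <- function(report, path) {
  calls <- report$calls
  tg <- report$targeted
  tg <- tg[!is.na(tg$genotype) & tg$genotype != "ABSENT", , drop = FALSE]
  rows <- rbind(
    if (nrow(calls)) data.frame(sample_id = report$sample_id,
                                label = calls$label,
                                genotype = calls$genotype,
                                mechanism = calls$mechanism,
                                cnv_class = report$cn_call$cnv_class),
    if (nrow(tg)) data.frame(sample_id = report$sample_id,
                             label = tg$label, genotype = tg$genotype,
                             mechanism = "SNV",
                             cnv_class = report$cn_call$cnv_class))
  if (is.null(rows))
    rows <- data.frame(sample_id = report$sample_id, label = "none",
                       genotype = "WT", mechanism = "none",
                       cnv_class = report$cn_call$cnv_class)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Print method for sample reports
#' @param x a `sample_report`.
#' @param ... unused.
#' @export
print.sample_report <- function(x, ...) {
  cat("Sample:", x$sample_id, "\n")
  cat(sprintf("  combined CN (gene+pseudogene): %d  [unique-region CN %d, %s, posterior %.3f]\n",
              x$cn_call$cn_total, x$cn_call$cn_unique,
              x$cn_call$cnv_class, x$cn_call$posterior))
  if (nrow(x$haplotypes)) {
    cat("  phased haplotypes (G=gene base, P=pseudogene base):\n")
    for (i in seq_len(nrow(x$haplotypes)))
      cat(sprintf("    %s  cn=%d  support=%d\n",
                  x$haplotypes$allele_string[i], x$haplotypes$cn[i],
                  x$haplotypes$support[i]))
  }
  if (!is.null(x$scenario$genotype) && !is.na(x$scenario$genotype))
    cat("  scenario:", x$scenario$genotype, "( wild-type copies:",
        x$scenario$wildtype_gba_copies, ")\n")
  if (nrow(x$calls)) {
    cat("  calls:\n")
    for (i in seq_len(nrow(x$calls)))
      cat(sprintf("    %-18s %-12s mechanism=%s%s\n", x$calls$label[i],
                  x$calls$genotype[i], x$calls$mechanism[i],
                  if (isTRUE(x$calls$pathogenic[i])) " [pathogenic]" else ""))
  } else cat("  calls: none (wild type in the phasing region)\n")
  invisible(x)
}
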