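## Direct genotyping of known target variants outside the exon 9-11
## homology region. Alignments there are trustworthy (the paralogs are not
## highly similar outside the homology block), so reads are filtered at
## MAPQ >= 20 and counted for reference vs alternate support; indels are
## recognized from CIGAR-declared events with positional slack.

#' Genotype known target variants from read support
#'
#' For every model variant with `in_homology_region = FALSE`, counts
#' alternate- and reference-supporting reads (MAPQ >= 20, fragment-level
#' deduplication) and calls the variant copy number as
#' `argmax_c Binom(k_alt; k_alt + k_ref, c / local_cn)` with the same
#' error-floor clamping as the site-CN estimator. Insertions and deletions
#' are counted from CIGAR events within `indel_slack` bp of the locus.
#'
#' @param bam path to an indexed BAM or a [load_reads()] data.frame.
#' @param model a [paralog_model()].
#' @param local_cn local copy-number context (default 2).
#' @param min_depth no-call below this ref+alt depth (default 10).
#' @param min_mapq mapping-quality filter (default 20).
#' @param min_base_quality base-quality filter (default 13).
#' @param indel_slack positional tolerance for indel events (default 2).
#' @param eps binomial error floor (default 0.01).
#' @return data.frame `label`, `k_alt`, `k_ref`, `k_other`, `genotype`
#'   ("ABSENT"/"HET"/"HOM"/NA for no-call), `variant_cn`, `posterior`.
#' @export
call_known_variants <- function(bam, model, local_cn = 2L, min_depth = 10L,
                                min_mapq = 20L, min_base_quality = 13L,
                                indel_slack = 2L, eps = 0.01) {
  reads <- if (is.data.frame(bam)) bam else load_reads(bam)
  v <- model$variants[!model$variants$in_homology_region, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(label = character(), k_alt = integer(),
                      k_ref = integer(), k_other = integer(),
                      genotype = character(), variant_cn = integer(),
                      posterior = numeric()))
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  events <- cigar_indel_events(reads)
  out <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    ref_a <- v$ref_allele[i]; alt_a <- v$alt_allele[i]
    p <- v$gene_pos[i]
    is_ins <- nchar(alt_a) > nchar(ref_a)
    is_del <- nchar(alt_a) < nchar(ref_a)
    bc <- collect_base_calls(reads, p, min_base_quality)
    bc <- bc[!duplicated(bc$qname), , drop = FALSE]
    if (is_ins || is_del) {
      ev <- events[events$op == (if (is_ins) "I" else "D") &
                     abs(events$ref_pos - (p + 1L)) <= indel_slack, ,
                   drop = FALSE]
      alt_qn <- unique(ev$qname)
      k_alt <- length(alt_qn)
      k_ref <- sum(!is.na(bc$base) & !(bc$qname %in% alt_qn))
      k_other <- 0L
    } else {
      k_alt <- sum(bc$base == alt_a, na.rm = TRUE)
      k_ref <- sum(bc$base == ref_a, na.rm = TRUE)
      k_other <- sum(!is.na(bc$base)) - k_alt - k_ref
    }
    n <- k_alt + k_ref
    if (n < min_depth) {
      out[[i]] <- data.frame(label = v$label[i], k_alt = k_alt,
                             k_ref = k_ref, k_other = k_other,
                             genotype = NA_character_,
                             variant_cn = NA_integer_,
                             posterior = NA_real_)
      next
    }
    cc <- 0:local_cn
    pr <- pmin(pmax(cc / local_cn, eps), 1 - eps)
    ll <- stats::dbinom(k_alt, n, pr)
    post <- ll / sum(ll)
    vc <- cc[which.max(post)]
    geno <- if (vc == 0L) "ABSENT" else if (vc == local_cn) "HOM" else "HET"
    out[[i]] <- data.frame(label = v$label[i], k_alt = k_alt,
                           k_ref = k_ref, k_other = k_other,
                           genotype = geno, variant_cn = vc,
                           posterior = max(post))
  }
  do.call(rbind, out)
}
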