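## Per-site gene copy number and breakpoint localization.
##
## At every differentiating site, reads are pooled over BOTH paralog
## positions, so a read carrying the gene base contributes identically
## whether the aligner put it on the gene or on the pseudogene. This makes
## the counts — and every downstream call — invariant to the paralog
## misalignment that defeats locus-naive pipelines. No mapping-quality
## filter is applied: reads in the homology region legitimately carry
## MAPQ 0.

#' Count gene/pseudogene base support at every differentiating site
#'
#' @param bam path to an indexed BAM, or a data.frame from [load_reads()].
#' @param model a [paralog_model()].
#' @param min_base_quality minimum base quality (default 13).
#' @return data.frame with `site_id`, `k_gene`, `k_pseudo`, `k_other`,
#'   `covered`. Fragments (mate pairs) are deduplicated by read name; a
#'   pair disagreeing at a site is dropped at that site.
#' @export
count_site_bases <- function(bam, model, min_base_quality = 13L) {
  reads <- if (is.data.frame(bam)) bam else load_reads(bam)
  s <- model$sites
  calls <- site_allele_calls(reads, model, min_base_quality)
  res <- data.frame(site_id = s$site_id, k_gene = 0L, k_pseudo = 0L,
                    k_other = 0L, covered = FALSE)
  if (nrow(calls)) {
    tab <- table(factor(calls$site_id, levels = s$site_id),
                 factor(calls$allele, levels = c("G", "P", "other")))
    res$k_gene <- as.integer(tab[, "G"])
    res$k_pseudo <- as.integer(tab[, "P"])
    res$k_other <- as.integer(tab[, "other"])
    res$covered <- rowSums(tab) > 0
  }
  res
}

## per-fragment allele call (G/P/other) at each site, pooled over both
## paralog positions and deduplicated by read name
site_allele_calls <- function(reads, model, min_base_quality = 13L,
                              sites = model$sites) {
  s <- sites
  pos_tab <- rbind(data.frame(pos = s$gene_pos, site_id = s$site_id),
                   data.frame(pos = s$pseudo_pos, site_id = s$site_id))
  bc <- collect_base_calls(reads, pos_tab$pos, min_base_quality)
  if (!nrow(bc))
    return(data.frame(site_id = integer(), qname = character(),
                      allele = character()))
  bc <- merge(bc, pos_tab, by = "pos")
  i <- match(bc$site_id, s$site_id)
  ## indel-type sites are typed from junction context: require the read
  ## to span the site with margin on both flanks, otherwise a read whose
  ## alignment merely starts at the junction votes without evidence
  margin <- 2L
  is_ind <- s$is_indel[i]
  spans <- bc$read_start <= bc$pos - margin & bc$read_end >= bc$pos + margin
  keep_ind <- !is_ind | spans
  bc <- bc[keep_ind, , drop = FALSE]
  i <- i[keep_ind]
  bc$allele <- ifelse(is.na(bc$base), "other",
               ifelse(bc$base == s$gene_base[i], "G",
               ifelse(bc$base == s$pseudo_base[i], "P", "other")))
  ## fragment-level dedup: same call once, conflicting calls dropped
  key <- paste(bc$site_id, bc$qname, sep = "\r")
  n_alleles <- tapply(bc$allele, key, function(a) length(unique(a)))
  first <- !duplicated(key)
  out <- bc[first, c("site_id", "qname", "allele")]
  ok <- n_alleles[paste(out$site_id, out$qname, sep = "\r")] == 1L
  out[ok, , drop = FALSE]
}

#' Estimate the gene copy number at one site
#'
#' `cn_gene = argmax_c Binom(k_gene; k_gene + k_pseudo, c / cn_total)` over
#' `c = 0..cn_total`, with the success probability clamped to
#' `[eps, 1 - eps]` so boundary copy numbers are not infinitely penalized
#' by a single stray read. Posterior from normalized likelihoods under a
#' flat prior.
#'
#' @param k_gene,k_pseudo read counts supporting the gene/pseudogene base.
#' @param cn_total combined gene+pseudogene copy number at the site.
#' @param eps error-rate floor (default 0.01).
#' @param min_site_depth no-call below this combined depth (default 10).
#' @return list `cn_gene`, `posterior`; `cn_gene` is NA on no-call.
#' @export
estimate_site_cn <- function(k_gene, k_pseudo, cn_total, eps = 0.01,
                             min_site_depth = 10L) {
  n <- k_gene + k_pseudo
  if (n < min_site_depth || cn_total < 1L)
    return(list(cn_gene = NA_integer_, posterior = NA_real_))
  cc <- 0:cn_total
  p <- pmin(pmax(cc / cn_total, eps), 1 - eps)
  ll <- stats::dbinom(k_gene, n, p)
  post <- ll / sum(ll)
  list(cn_gene = cc[which.max(post)], posterior = max(post))
}

#' Gene copy number along all differentiating sites
#'
#' @param counts data.frame from [count_site_bases()].
#' @param cn_total combined copy number from [call_total_cn()].
#' @param model optional model; unreliable sites are masked to no-call.
#' @inheritParams estimate_site_cn
#' @return A `site_cn_series`: data.frame `site_id`, `cn_gene`,
#'   `posterior`, with attribute `cn_total`.
#' @export
site_cn_series <- function(counts, cn_total, model = NULL, eps = 0.01,
                           min_site_depth = 10L) {
  est <- lapply(seq_len(nrow(counts)), function(i)
    estimate_site_cn(counts$k_gene[i], counts$k_pseudo[i], cn_total,
                     eps, min_site_depth))
  out <- data.frame(site_id = counts$site_id,
                    cn_gene = vapply(est, `[[`, 0L, "cn_gene"),
                    posterior = vapply(est, `[[`, 0, "posterior"),
                    k_gene = counts$k_gene,
                    n = counts$k_gene + counts$k_pseudo)
  if (!is.null(model)) {
    bad <- model$sites$site_id[!model$sites$reliable]
    out$cn_gene[out$site_id %in% bad] <- NA_integer_
  }
  attr(out, "cn_total") <- as.integer(cn_total)
  class(out) <- c("site_cn_series", "data.frame")
  out
}

site_ll <- function(k, n, p) {
  p <- min(max(p, 0.01), 0.99)
  k * log(p) + (n - k) * log(1 - p)
}

#' Detect copy-number transitions along the site series
#'
#' Localizes CNV breakpoints and conversion segments as changepoints in
#' the pooled gene-base fraction, fitted by maximum likelihood under the
#' pattern the CNV class implies. A CNL or CNG sample has exactly one step
#' — from 2 gene copies to `cn_total - 2` — whose position is the argmax
#' of the binomial changepoint likelihood over all inter-site positions.
#' Without a CNV, a gene-conversion segment is a contiguous dip from 2
#' gene copies to 1 (or 0 for a homozygous conversion), found as the
#' maximum-scoring subarray of per-site log-likelihood-ratio scores and
#' accepted only when the dip improves the constant model by more than
#' `conv_threshold` log units (default 25, calibrated so coverage noise never fakes a segment) — coverage fluctuations are spatially
#' correlated across neighbouring sites (one fragment spans a whole site
#' cluster), so per-site copy-number flips are never interpreted
#' directly.
#'
#' @param series a `site_cn_series` (carries the pooled counts).
#' @param cnv_class "CNL", "NONE" or "CNG" from [call_total_cn()].
#' @param model optional model; adds genomic positions to the intervals.
#' @param conv_threshold minimum log-likelihood gain to call a conversion
#'   segment (default 25).
#' @return data.frame of breakpoint calls: `kind` ("CNL", "CNG",
#'   "CONVERSION_START", "CONVERSION_END"), `left_site`, `right_site`
#'   (adjacent informative sites bracketing the changepoint, open
#'   interval), `cn_before`, `cn_after`, and gene positions when a model
#'   is given.
#' @export
detect_cn_transitions <- function(series, cnv_class = "NONE", model = NULL,
                                  conv_threshold = 25) {
  cn_total <- attr(series, "cn_total")
  called <- series[!is.na(series$cn_gene) & series$n > 0, , drop = FALSE]
  empty <- data.frame(kind = character(), left_site = integer(),
                      right_site = integer(), cn_before = integer(),
                      cn_after = integer(), left_pos = integer(),
                      right_pos = integer())
  annotate <- function(out) {
    if (!nrow(out)) return(out)
    if (!is.null(model)) {
      out$left_pos <- model$sites$gene_pos[match(out$left_site,
                                                 model$sites$site_id)]
      out$right_pos <- model$sites$gene_pos[match(out$right_site,
                                                  model$sites$site_id)]
    } else {
      out$left_pos <- NA_integer_; out$right_pos <- NA_integer_
    }
    out
  }
  S <- nrow(called)
  if (S < 2L) return(empty)
  k <- called$k_gene; n <- called$n

  if (cnv_class %in% c("CNL", "CNG")) {
    cn_after <- cn_total - 2L
    p1 <- 2 / cn_total; p2 <- cn_after / cn_total
    gain <- vapply(seq_len(S), function(i) site_ll(k[i], n[i], p2) -
                     site_ll(k[i], n[i], p1), 0)
    ## changepoint after position j: sites j+1..S in the 'after' regime
    suffix <- rev(cumsum(rev(gain)))
    j <- which.max(suffix[-1L])  # at least one site on each side
    out <- data.frame(kind = cnv_class,
                      left_site = called$site_id[j],
                      right_site = called$site_id[j + 1L],
                      cn_before = 2L, cn_after = cn_after)
    return(annotate(out))
  }

  ## no CNV: search for a conversion dip (2 -> 1 or 2 -> 0 gene copies)
  best <- NULL; best_gain <- 0
  for (dip_cn in c(1L, 0L)) {
    sc <- vapply(seq_len(S), function(i)
      site_ll(k[i], n[i], dip_cn / cn_total) -
        site_ll(k[i], n[i], 2 / cn_total), 0)
    ## maximum-scoring subarray (Kadane), tracking boundaries
    cur <- 0; cur_a <- 1L; top <- 0; top_a <- 0L; top_b <- 0L
    for (i in seq_len(S)) {
      if (cur <= 0) { cur <- 0; cur_a <- i }
      cur <- cur + sc[i]
      if (cur > top) { top <- cur; top_a <- cur_a; top_b <- i }
    }
    if (top > best_gain) {
      best_gain <- top
      best <- c(top_a, top_b, dip_cn)
    }
  }
  if (is.null(best) || best_gain < conv_threshold) return(empty)
  a <- best[1L]; b <- best[2L]; dip_cn <- best[3L]
  out <- rbind(
    data.frame(kind = "CONVERSION_START",
               left_site = called$site_id[max(a - 1L, 1L)],
               right_site = called$site_id[a],
               cn_before = 2L, cn_after = dip_cn),
    data.frame(kind = "CONVERSION_END",
               left_site = called$site_id[b],
               right_site = called$site_id[min(b + 1L, S)],
               cn_before = dip_cn, cn_after = 2L))
  annotate(out)
}

#' Classify a CNL breakpoint as pathogenic or not
#'
#' A fusion deletion is pathogenic when its breakpoint interval can fall
#' inside the gene coding region. The open interval between the bracketing
#' sites is intersected with the coding region; an interval straddling the
#' coding 3' boundary is classified pathogenic (the costlier error is
#' false reassurance) and flagged as a boundary case.
#'
#' @param bp one row of the [detect_cn_transitions()] output with
#'   `left_pos`/`right_pos` filled in.
#' @param model a [paralog_model()].
#' @return list `pathogenic` (logical) and `boundary` (logical).
#' @export
classify_cnl_pathogenicity <- function(bp, model) {
  if (bp$kind != "CNL") stop("not a CNL breakpoint")
  cs <- model$coding_region$start; ce <- model$coding_region$end
  lo <- bp$left_pos + 1L; hi <- bp$right_pos - 1L
  overlaps <- lo < ce && hi >= cs
  fully_inside <- lo >= cs && hi < ce
  list(pathogenic = overlaps, boundary = overlaps && !fully_inside)
}
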