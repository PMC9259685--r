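## Copy-number calling from depth in the unique inter-paralog region.
##
## The combined gene+pseudogene copy number cannot be read from depth over
## the paralogs themselves (reads interchange freely between them), but the
## unique region between the paralogs is present once per recombination
## unit: its depth, normalized against baseline windows and corrected for
## GC content, scales linearly with the unit copy number. An
## integer-centered Gaussian mixture turns the normalized depth into an
## integer copy number with a posterior.

#' Extract binned depth over the unique CN region and baseline windows
#'
#' Mean per-bp depth is computed per bin from primary, non-duplicate
#' alignments; each bin also carries its reference GC fraction for the GC
#' correction step.
#'
#' @param bam path to an indexed BAM, or a data.frame from [load_reads()].
#' @param model a [paralog_model()] with non-empty `baseline_regions`.
#' @param ref_seq reference sequence as a character scalar, or a FASTA path.
#' @param bin_size bin width in bp (default 200).
#' @return A `depth_profile`: data.frame `bins` with `start`, `end`,
#'   `raw_depth`, `gc_fraction`, `region` ("unique"/"baseline"), plus
#'   attributes tracking correction state.
#' @export
extract_depth <- function(bam, model, ref_seq, bin_size = 200L) {
  reads <- if (is.data.frame(bam)) bam else load_reads(bam)
  if (!nrow(reads)) stop("degenerate input: no usable alignments in BAM")
  if (!length(model$baseline_regions))
    stop("model has no baseline_regions for normalization")
  seqchr <- load_ref_seq(ref_seq)

  bin_iv <- function(iv, region) {
    b0 <- seq.int(iv$start, iv$end - 1L, by = bin_size)
    b1 <- pmin(b0 + bin_size, iv$end)
    full <- (b1 - b0) == bin_size
    data.frame(start = b0[full], end = b1[full], region = region)
  }
  bins <- rbind(bin_iv(model$unique_cn_region, "unique"),
                do.call(rbind, lapply(model$baseline_regions, bin_iv,
                                      region = "baseline")))
  bins$raw_depth <- bin_mean_depth(reads, bins$start, bins$end)
  bins$gc_fraction <- bin_gc(seqchr, bins$start, bins$end)
  if (all(bins$raw_depth[bins$region == "baseline"] == 0))
    stop("degenerate input: zero baseline coverage")
  structure(list(bins = bins, corrected = FALSE, gc_skipped = FALSE),
            class = "depth_profile")
}

load_ref_seq <- function(ref_seq) {
  if (nchar(ref_seq[1]) < 1000L && file.exists(ref_seq[1])) {
    x <- Biostrings::readDNAStringSet(ref_seq[1])
    as.character(x[[1]])
  } else ref_seq[1]
}

bin_mean_depth <- function(reads, b0, b1) {
  starts <- reads$pos; ends <- reads$end
  maxw <- max(reads$rwidth)
  vapply(seq_along(b0), function(i) {
    lo <- findInterval(b0[i] - maxw, starts) + 1L
    hi <- findInterval(b1[i] - 1L, starts)
    if (hi < lo) return(0)
    j <- lo:hi
    ov <- pmin(ends[j] + 1L, b1[i]) - pmax(starts[j], b0[i])
    sum(ov[ov > 0]) / (b1[i] - b0[i])
  }, 0)
}

bin_gc <- function(seqchr, b0, b1) {
  sub <- substring(seqchr, b0 + 1L, b1)
  gc <- vapply(sub, function(s) {
    r <- charToRaw(s)
    sum(r == charToRaw("G") | r == charToRaw("C")) / length(r)
  }, 0)
  unname(gc)
}

#' GC-correct a depth profile
#'
#' A correction is applied only when the baseline bins show a significant
#' depth~GC trend (p < 1e-4); an unconditional correction would inject
#' stratum-median sampling noise into unbiased samples. When correcting,
#' bins are assigned to 2%-wide GC strata; each bin's depth is divided by
#' the lowess-smoothed median baseline depth of its stratum (empty strata
#' borrow the nearest populated one) and rescaled so the overall baseline
#' median is unchanged. With fewer than 20 baseline bins or fewer than 3
#' occupied strata the correction is skipped and the profile flagged.
#'
#' @param profile a `depth_profile` from [extract_depth()].
#' @return The corrected `depth_profile` (`corrected = TRUE`, or
#'   `gc_skipped = TRUE` with a warning when the baseline cannot support a
#'   correction).
#' @export
gc_correct <- function(profile) {
  b <- profile$bins
  bl <- b[b$region == "baseline", ]
  strat <- function(gc) as.integer(floor(gc * 50))  # 2% strata
  sb <- strat(bl$gc_fraction)
  occupied <- sort(unique(sb))
  if (nrow(bl) < 20L || length(occupied) < 3L) {
    warning("GC correction skipped: baseline spans too few GC strata")
    profile$gc_skipped <- TRUE
    profile$corrected <- TRUE
    return(profile)
  }
  ## correct only when the baseline shows a significant depth~GC trend:
  ## with desk-scale baselines an unconditional stratum-median correction
  ## would inject its own sampling noise into unbiased data
  fit <- stats::lm(raw_depth ~ gc_fraction, data = bl)
  pval <- summary(fit)$coefficients[2, 4]
  if (is.na(pval) || pval > 1e-4) {
    profile$corrected <- TRUE
    return(profile)
  }
  med <- vapply(occupied, function(s) stats::median(bl$raw_depth[sb == s]),
                0)
  ## smooth the stratum medians across GC before using them as divisors
  if (length(occupied) >= 4L) {
    sm <- stats::lowess(occupied, med, f = 0.75)
    med <- sm$y[match(occupied, sm$x)]
  }
  overall <- stats::median(bl$raw_depth)
  sa <- strat(b$gc_fraction)
  nearest <- occupied[vapply(sa, function(s)
    which.min(abs(occupied - s)), 0L)]
  denom <- med[match(nearest, occupied)]
  denom[is.na(denom) | denom <= 0] <- overall
  b$raw_depth <- b$raw_depth / denom * overall
  profile$bins <- b
  profile$corrected <- TRUE
  profile
}

#' Normalize depth to copy-number scale
#'
#' Computes `d = 2 * trimmed_mean(unique bins) / trimmed_mean(baseline
#' bins)` (5% trimmed at each end), so a diploid sample without CNVs has
#' expectation 2.
#'
#' @param profile a GC-corrected `depth_profile`.
#' @return A `normalized_depth` list: `d` and `n_bins_used`.
#' @export
normalize_depth <- function(profile) {
  if (!isTRUE(profile$corrected))
    stop("profile must be GC-corrected first (see gc_correct)")
  b <- profile$bins
  u <- b$raw_depth[b$region == "unique"]
  bl <- b$raw_depth[b$region == "baseline"]
  mb <- mean(bl, trim = 0.05)
  if (mb <= 0) stop("baseline trimmed mean is zero")
  structure(list(d = 2 * mean(u, trim = 0.05) / mb,
                 n_bins_used = length(u) + length(bl)),
            class = "normalized_depth")
}

#' Call total combined copy number from normalized depth
#'
#' MAP call under a Gaussian mixture with components centered at the
#' integers `0..max_cn`, component SD `sigma0 * sqrt(max(k, 1))` and a flat
#' prior. The unique-region copy number plus two gives the combined
#' gene+pseudogene copy number.
#'
#' @param nd a `normalized_depth` or a bare numeric depth value.
#' @param max_cn largest component (default 10, must be >= 8).
#' @param sigma0 diploid-scale component SD (default 0.12).
#' @param posterior_threshold no-call below this posterior (default 0.95).
#' @return A `copy_number_call`: `cn_unique`, `cn_total`, `posterior`,
#'   `cnv_class` ("CNL"/"NONE"/"CNG"), `no_call`, `d`.
#' @export
call_total_cn <- function(nd, max_cn = 10L, sigma0 = 0.12,
                          posterior_threshold = 0.95) {
  d <- if (inherits(nd, "normalized_depth")) nd$d else as.numeric(nd)
  stopifnot(is.finite(d), max_cn >= 8L)
  k <- 0:max_cn
  dens <- stats::dnorm(d, mean = k, sd = sigma0 * sqrt(pmax(k, 1)))
  post <- dens / sum(dens)
  cn <- k[which.max(post)]
  p <- max(post)
  cls <- if (cn <= 1L) "CNL" else if (cn == 2L) "NONE" else "CNG"
  structure(list(cn_unique = cn, cn_total = cn + 2L, posterior = p,
                 cnv_class = cls, no_call = p < posterior_threshold, d = d),
            class = "copy_number_call")
}
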