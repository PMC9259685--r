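## Long-read amplicon companion procedures: primer-pair allele logic,
## sentinel-site breakpoint bracketing, homopolymer depth-anomaly
## detection and genotype-quality filtering of small-variant calls.

#' Classify an allele from primer-pair amplification evidence
#'
#' Three primer pairs distinguish the recombinant allele classes: pair 1
#' amplifies the intact gene, pair 2 only a fusion-deletion (CNL) allele,
#' pair 3 only a duplication-hybrid (CNG) allele.
#'
#' @param amplified named logical vector with elements `pair1`, `pair2`,
#'   `pair3`.
#' @return One of `"WT_or_conversion"`, `"CNL"`, `"CNG"`, `"MIXED"`.
#' @export
classify_allele_from_primers <- function(amplified) {
  p1 <- isTRUE(amplified[["pair1"]])
  p2 <- isTRUE(amplified[["pair2"]])
  p3 <- isTRUE(amplified[["pair3"]])
  if (p3 && !p1)
    stop("inconsistent evidence: pair 3 amplifies only when the intact ",
         "gene (pair 1) is present")
  if (!p1 && !p2) stop("no amplification from any primer pair")
  if (p2 && !p1) return("CNL")
  if (p1 && p2) return("MIXED")
  if (p1 && p3) return("CNG")
  "WT_or_conversion"
}

#' Bracket a CNL breakpoint from sentinel-site calls
#'
#' Along a fusion amplicon the sentinel (differentiating) sites read GENE
#' 5' of the breakpoint and PSEUDO 3' of it. The breakpoint is returned as
#' the open interval between the last GENE sentinel and the first PSEUDO
#' sentinel, skipping NOCALL sites. If the PSEUDO calls do not form a
#' contiguous 3' suffix the call is flagged non-canonical and every
#' transition interval is listed.
#'
#' @param status character vector of `"GENE"`, `"PSEUDO"`, `"NOCALL"` in
#'   5'->3' order.
#' @param site_ids optional identifiers parallel to `status` (defaults to
#'   positional indices).
#' @return list with `interval = c(left, right)` (site ids, open),
#'   `non_canonical` flag, and `transitions` (all G->P/P->G intervals).
#' @export
locate_cnl_breakpoint <- function(status, site_ids = seq_along(status)) {
  stopifnot(length(status) == length(site_ids))
  keep <- status != "NOCALL"
  st <- status[keep]; ids <- site_ids[keep]
  if (!length(st) || all(st == "GENE"))
    stop("no breakpoint: no PSEUDO sentinel detected")
  if (all(st == "PSEUDO"))
    stop("no breakpoint: all sentinels PSEUDO (wrong amplicon?)")
  chg <- which(st[-1] != st[-length(st)])
  transitions <- lapply(chg, function(i) c(ids[i], ids[i + 1L]))
  canonical <- length(chg) == 1L && st[1L] == "GENE" &&
    st[length(st)] == "PSEUDO"
  list(interval = transitions[[1L]],
       non_canonical = !canonical,
       transitions = transitions)
}

#' Detect homopolymer variants from run-level depth anomalies
#'
#' Homopolymer indels and SNVs distort local amplicon depth. For each
#' sample and homopolymer position the depth is adjusted by the mean depth
#' over the 100 flanking positions; a sample whose adjusted depth deviates
#' from the median of the other samples in the run by more than `tau_mad`
#' (scaled) median absolute deviations is flagged: DELETION when below the
#' run median, SNV when above.
#'
#' @param run a `run_depth_matrix` (see [simulate_run_depths()]) or a list
#'   with `pos_depth` and `flank_depth` matrices (samples x positions).
#' @param tau_mad threshold in MADs (default 5).
#' @param mad_constant normal-consistency scaling (default 1.4826).
#' @param fallback_rel relative-deviation threshold used when the MAD is
#'   zero (default 0.2, with a warning).
#' @return character matrix (samples x positions) of
#'   `"NONE"`/`"DELETION"`/`"SNV"` flags.
#' @export
detect_homopolymer_variants <- function(run, tau_mad = 5,
                                        mad_constant = 1.4826,
                                        fallback_rel = 0.2) {
  a <- run$pos_depth / run$flank_depth
  n <- nrow(a); P <- ncol(a)
  if (n < 3L) stop("need >= 3 samples per run for MAD statistics")
  if (any(run$flank_depth <= 0)) stop("flanking depth must be positive")
  flags <- matrix("NONE", n, P)
  warned <- FALSE
  for (p in seq_len(P)) {
    for (s in seq_len(n)) {
      others <- a[-s, p]
      med <- stats::median(others)
      md <- stats::mad(others, constant = mad_constant)
      if (md == 0) {
        if (!warned) {
          warning("MAD is zero; falling back to a ", fallback_rel * 100,
                  "% relative-deviation threshold")
          warned <- TRUE
        }
        dev <- (a[s, p] - med) / med
        if (abs(dev) > fallback_rel)
          flags[s, p] <- if (dev < 0) "DELETION" else "SNV"
      } else {
        z <- (a[s, p] - med) / md
        if (abs(z) > tau_mad)
          flags[s, p] <- if (z < 0) "DELETION" else "SNV"
      }
    }
  }
  flags
}

#' Filter small-variant calls by genotype quality
#'
#' @param records data.frame of variant records carrying a `gq` (or `GQ`)
#'   column, or a `vcfR` object from which per-sample GQ is extracted.
#' @param threshold minimum genotype quality kept (default 650).
#' @return The records with `gq >= threshold`; attribute `n_removed`
#'   counts the filtered records. A missing score field passes everything
#'   through with a warning.
#' @export
filter_variants_by_gq <- function(records, threshold = 650) {
  if (inherits(records, "vcfR")) {
    gq <- suppressWarnings(
      as.numeric(vcfR::extract.gt(records, element = "GQ")[, 1L]))
    fix <- as.data.frame(records@fix, stringsAsFactors = FALSE)
    records <- cbind(fix, gq = gq)
  }
  gq_col <- intersect(c("gq", "GQ"), names(records))[1]
  if (is.na(gq_col) || is.null(gq_col)) {
    warning("no GQ field found; records passed through unfiltered")
    attr(records, "n_removed") <- 0L
    return(records)
  }
  keep <- !is.na(records[[gq_col]]) & records[[gq_col]] >= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
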