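## Thin read-access layer over Rsamtools. All positions 0-based internally.

#' Load primary alignments from a BAM file
#'
#' Reads primary, non-duplicate, non-supplementary alignments and returns
#' them as a data.frame ready for depth, site-count and phasing extraction.
#'
#' @param bam path to an indexed BAM.
#' @param region optional `genomic_interval` restricting the fetch.
#' @return data.frame with `qname`, `flag`, `pos` (0-based leftmost),
#'   `mapq`, `cigar`, `seq`, `qual`, `rwidth` (reference span) and `end`
#'   (0-based last aligned base).
#' @export
load_reads <- function(bam, region = NULL) {
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  what <- c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(flag = flags, what = what)
  } else {
    rng <- GRanges_like(region)
    Rsamtools::ScanBamParam(flag = flags, what = what, which = rng)
  }
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  df <- data.frame(qname = res$qname, flag = res$flag,
                   pos = res$pos - 1L, mapq = res$mapq, cigar = res$cigar,
                   seq = as.character(res$seq),
                   qual = as.character(res$qual),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$pos), , drop = FALSE]
  df$rwidth <- cigar_ref_width(df$cigar)
  df$end <- df$pos + df$rwidth - 1L
  df[order(df$pos), , drop = FALSE]
}

GRanges_like <- function(iv) {
  ## IRanges is an Rsamtools dependency; 1-based closed coordinates
  rng <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  nm <- iv$contig
  rngl <- IRanges::IRangesList(rng)
  names(rngl) <- nm
  rngl
}

cigar_ref_width <- function(cigar) {
  w <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  w[simple] <- as.integer(sub("M$", "", cigar[simple]))
  for (i in which(!simple)) {
    ops <- parse_cigar(cigar[i])
    w[i] <- sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }
  w
}

parse_cigar <- function(cig) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cig)[[1]]
  toks <- regmatches(cig, list(m))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

## base + quality carried by one read at reference position p, or NA
read_base_at <- function(pos, cigar, seq, qual, p) {
  if (grepl("^[0-9]+M$", cigar)) {
    off <- p - pos
    return(c(substr(seq, off + 1L, off + 1L),
             substr(qual, off + 1L, off + 1L)))
  }
  ops <- parse_cigar(cigar)
  refc <- pos; qoff <- 0L
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      if (p >= refc && p < refc + len) {
        i <- qoff + (p - refc) + 1L
        return(c(substr(seq, i, i), substr(qual, i, i)))
      }
      refc <- refc + len; qoff <- qoff + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      if (p >= refc && p < refc + len) return(c(NA_character_,
                                                NA_character_))
      refc <- refc + len
    }
  }
  c(NA_character_, NA_character_)
}

#' Collect per-read base calls at a set of reference positions
#'
#' @param reads data.frame from [load_reads()].
#' @param positions 0-based reference positions.
#' @param min_base_quality minimum Phred base quality (default 13).
#' @return data.frame `pos`, `qname`, `mapq`, `base` (NA for a spanning
#'   deletion).
#' @export
collect_base_calls <- function(reads, positions, min_base_quality = 13L) {
  if (!nrow(reads))
    return(data.frame(pos = integer(), qname = character(),
                      mapq = integer(), base = character(),
                      read_start = integer(), read_end = integer()))
  starts <- reads$pos
  maxw <- max(reads$rwidth)
  out <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    p <- positions[i]
    lo <- findInterval(p - maxw, starts) + 1L
    hi <- findInterval(p, starts)
    if (hi < lo) next
    cand <- lo:hi
    cand <- cand[reads$end[cand] >= p]
    if (!length(cand)) next
    bq <- vapply(cand, function(j)
      read_base_at(reads$pos[j], reads$cigar[j], reads$seq[j],
                   reads$qual[j], p), c("", ""))
    base <- bq[1L, ]; qual <- bq[2L, ]
    keep <- is.na(qual) |
      (utf8ToInt_safe(qual) - 33L) >= min_base_quality
    out[[i]] <- data.frame(pos = p, qname = reads$qname[cand][keep],
                           mapq = reads$mapq[cand][keep],
                           base = base[keep],
                           read_start = reads$pos[cand][keep],
                           read_end = reads$end[cand][keep],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)]) %||%
    data.frame(pos = integer(), qname = character(), mapq = integer(),
               base = character(), read_start = integer(),
               read_end = integer())
}

utf8ToInt_safe <- function(ch) {
  v <- integer(length(ch))
  ok <- !is.na(ch) & nzchar(ch)
  v[ok] <- vapply(ch[ok], utf8ToInt, 0L)
  v[!ok] <- NA_integer_
  v
}

## insertion/deletion events declared by CIGARs, with reference coordinates
cigar_indel_events <- function(reads) {
  cplx <- which(!grepl("^[0-9]+M$", reads$cigar))
  out <- list()
  for (i in cplx) {
    ops <- parse_cigar(reads$cigar[i])
    refc <- reads$pos[i]
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("I")) {
        out[[length(out) + 1L]] <-
          data.frame(qname = reads$qname[i], mapq = reads$mapq[i],
                     op = "I", ref_pos = refc, len = len)
      } else if (op %in% c("D", "N")) {
        out[[length(out) + 1L]] <-
          data.frame(qname = reads$qname[i], mapq = reads$mapq[i],
                     op = "D", ref_pos = refc, len = len)
        refc <- refc + len
      } else if (op %in% c("M", "=", "X")) {
        refc <- refc + len
      }
    }
  }
  do.call(rbind, out) %||%
    data.frame(qname = character(), mapq = integer(), op = character(),
               ref_pos = integer(), len = integer())
}
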