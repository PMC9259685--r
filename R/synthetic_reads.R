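## Paired-end read simulator over the mini reference.
##
## Reads are not passed through an external aligner. Instead each read is
## placed by a paralog-ambiguity rule that reproduces the one property of
## real alignments that matters to the callers: a read whose sequence is
## compatible with both paralogs is assigned to the location with fewer
## mismatches, and on an exact tie it is placed at the gene position with
## mapping quality 0.

#' Allele specifications for the simulator
#'
#' Constructors for the allele classes a parental haplotype can carry:
#' wild type, a known small variant, a gene-conversion segment, a fusion
#' deletion (CNL), a duplication (CNG) and the reverse-conversion decoys
#' (pseudogene haplotypes partially converted to gene sequence).
#'
#' @param label variant label present in the model (e.g. `"p.L483P"`).
#' @param from_site,to_site global `site_id` bounds of a converted segment
#'   (inclusive).
#' @param breakpoint 0-based gene position of the recombination breakpoint.
#' @param extra_copies number of extra unit copies for a CNG (1-6).
#' @param site_id global `site_id` of the decoy-converted pseudogene site.
#' @return A list describing the allele, consumed by [simulate_sample()].
#' @name allele_specs
NULL

#' @rdname allele_specs
#' @export
allele_wt <- function() list(kind = "WT")

#' @rdname allele_specs
#' @export
allele_snv <- function(label) list(kind = "SNV", label = label)

#' @rdname allele_specs
#' @export
allele_conversion <- function(from_site, to_site)
  list(kind = "CONVERSION", from_site = as.integer(from_site),
       to_site = as.integer(to_site))

#' @rdname allele_specs
#' @export
allele_cnl <- function(breakpoint)
  list(kind = "CNL", breakpoint = as.integer(breakpoint))

#' @rdname allele_specs
#' @export
allele_cng <- function(breakpoint, extra_copies) {
  if (!extra_copies %in% 1:6) stop("extra_copies must be in 1..6")
  list(kind = "CNG", breakpoint = as.integer(breakpoint),
       extra_copies = as.integer(extra_copies))
}

#' @rdname allele_specs
#' @export
allele_reverse_snv <- function(site_id)
  list(kind = "REVERSE_SNV", site_id = as.integer(site_id))

#' @rdname allele_specs
#' @export
allele_reverse_indel <- function() list(kind = "REVERSE_INDEL")

#' Simulation configuration
#'
#' @param depth mean total coverage (split evenly across the two parental
#'   haplotypes).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment-length distribution.
#' @param error_rate per-base substitution error rate.
#' @param gc_bias linear depth bias: relative depth change per +10
#'   percentage points of fragment GC (0 = unbiased).
#' @param seed mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(depth = 30, read_len = 150L, insert_mean = 400,
                       insert_sd = 60, error_rate = 0.002, gc_bias = 0,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(depth > 0, read_len > 0, insert_mean > 0, insert_sd > 0,
            error_rate >= 0)
  list(depth = depth, read_len = as.integer(read_len),
       insert_mean = insert_mean, insert_sd = insert_sd,
       error_rate = error_rate, gc_bias = gc_bias, seed = as.integer(seed))
}

## ---- haplotype construction -------------------------------------------

build_haplotype <- function(ref, specs) {
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
  refpos <- seq.int(0L, length(chars) - 1L)
  s <- ref$model$sites
  ins <- ref$insert
  excise_insert <- function(keepmask) {
    drop <- refpos >= ins$start & refpos < ins$end
    keepmask & !drop
  }
  structural <- Filter(function(x) x$kind %in% c("CNL", "CNG"), specs)
  if (length(structural) > 1L)
    stop("at most one structural allele per haplotype")
  for (sp in structural) {
    bp <- sp$breakpoint
    bpp <- ref$g2p[bp + 1L]
    if (is.na(bpp)) stop("breakpoint has no pseudogene homolog: ", bp)
    if (sp$kind == "CNL") {
      keep <- refpos < bp | refpos >= bpp
      chars <- chars[keep]; refpos <- refpos[keep]
    } else {
      unit <- which(refpos >= bp & refpos < bpp)
      pre <- which(refpos < bpp); post <- which(refpos >= bpp)
      idx <- c(pre, rep(unit, sp$extra_copies), post)
      chars <- chars[idx]; refpos <- refpos[idx]
    }
  }
  for (sp in specs) {
    if (sp$kind %in% c("CNL", "CNG", "WT")) next
    if (sp$kind == "SNV") {
      v <- ref$model$variants
      i <- match(sp$label, v$label)
      if (is.na(i)) stop("unknown variant label: ", sp$label)
      if (sp$label == "c.1263del55") {
        keep <- !(refpos >= ins$start & refpos < ins$end)
        chars <- chars[keep]; refpos <- refpos[keep]
      } else if (nchar(v$alt_allele[i]) > nchar(v$ref_allele[i])) {
        extra <- substring(v$alt_allele[i], 2L)  # e.g. c.84dupG
        j <- match(v$gene_pos[i], refpos)
        chars <- append(chars, strsplit(extra, "")[[1]], after = j)
        refpos <- append(refpos, rep(NA_integer_, nchar(extra)), after = j)
      } else {
        j <- match(v$gene_pos[i], refpos)
        chars[j] <- v$alt_allele[i]
      }
    } else if (sp$kind == "CONVERSION") {
      rng <- range(s$gene_pos[s$site_id %in% sp$from_site:sp$to_site])
      conv <- s[s$gene_pos >= rng[1] & s$gene_pos <= rng[2], , drop = FALSE]
      for (k in seq_len(nrow(conv))) {
        if (conv$is_indel[k]) {
          keep <- !(refpos >= ins$start & refpos < ins$end)
          chars <- chars[keep]; refpos <- refpos[keep]
        } else {
          j <- match(conv$gene_pos[k], refpos)
          if (!is.na(j)) chars[j] <- conv$pseudo_base[k]
        }
      }
    } else if (sp$kind == "REVERSE_SNV") {
      i <- match(sp$site_id, s$site_id)
      j <- match(s$pseudo_pos[i], refpos)
      chars[j] <- s$gene_base[i]
    } else if (sp$kind == "REVERSE_INDEL") {
      junction <- s$pseudo_pos[s$is_indel][1]
      j <- match(junction, refpos)
      inschars <- strsplit(ins$seq, "")[[1]]
      chars <- append(chars, inschars, after = j - 1L)
      refpos <- append(refpos, seq.int(ins$start, ins$end - 1L),
                       after = j - 1L)
    } else stop("unknown allele kind: ", sp$kind)
  }
  list(seq = paste(chars, collapse = ""), chars = chars, refpos = refpos)
}

str_mismatch <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  sum(ra != rb)
}

## place one non-contiguous (junction/insert-spanning) read; returns list or NULL
place_junction_read <- function(rp, readseq, ref, refseq, rl) {
  gene <- ref$model$gene; ps <- ref$model$pseudogene
  if (anyNA(rp)) {  # contains a non-reference insertion (c.84dupG)
    ok <- !is.na(rp)
    if (!any(ok)) return(NULL)
    runs <- rle(ok)
    cig <- character(0)
    i <- 1L
    for (k in seq_along(runs$lengths)) {
      n <- runs$lengths[k]
      if (runs$values[k]) cig <- c(cig, paste0(n, "M"))
      else cig <- c(cig, paste0(n, if (k == 1L ||
                                       k == length(runs$lengths)) "S" else "I"))
      i <- i + n
    }
    return(list(pos = rp[which(ok)[1]], cigar = paste(cig, collapse = ""),
                mapq = 60L))
  }
  in_gene <- rp >= gene$start & rp < gene$end
  in_ps <- rp >= ps$start & rp < ps$end
  if (!all(in_gene | in_ps)) {
    if (all(diff(rp) == 1L))
      return(list(pos = rp[1], cigar = paste0(rl, "M"), mapq = 60L))
    return(NULL)
  }
  gmap <- ifelse(in_gene, rp, ref$p2g[rp + 1L])
  pmap <- ifelse(in_ps, rp, ref$g2p[rp + 1L])
  g_ok <- !anyNA(gmap) && all(diff(gmap) == 1L)
  p_ok <- !anyNA(pmap) && all(diff(pmap) == 1L)
  if (g_ok && p_ok) {
    mg <- str_mismatch(readseq, substr(refseq, gmap[1] + 1L, gmap[1] + rl))
    mp <- str_mismatch(readseq, substr(refseq, pmap[1] + 1L, pmap[1] + rl))
    if (mg < mp) return(list(pos = gmap[1], cigar = paste0(rl, "M"),
                             mapq = 60L))
    if (mp < mg) return(list(pos = pmap[1], cigar = paste0(rl, "M"),
                             mapq = 60L))
    return(list(pos = gmap[1], cigar = paste0(rl, "M"), mapq = 0L))
  }
  if (g_ok) return(list(pos = gmap[1], cigar = paste0(rl, "M"), mapq = 60L))
  if (p_ok) return(list(pos = pmap[1], cigar = paste0(rl, "M"), mapq = 60L))
  NULL
}

#' Simulate an aligned short-read sample
#'
#' Builds the two parental haplotype sequences from allele specifications,
#' fragments them into paired-end reads, adds sequencing errors and GC bias,
#' places every read by the paralog-ambiguity rule, and writes a sorted,
#' indexed BAM plus a ground-truth record.
#'
#' @param ref a [build_mini_reference()] object.
#' @param hap1,hap2 lists of allele specifications (see [allele_specs]) for
#'   the two parental haplotypes; `list()` means wild type.
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param sample_id sample name used for file names and read names.
#' @return List with `bam` (path), `truth` (list: `cn_unique`, `cnv_class`,
#'   `breakpoints`, `variants`), and `sample_id`. The truth record is also
#'   written as `<sample_id>.truth.json`.
#' @export
simulate_sample <- function(ref, hap1 = list(), hap2 = list(), cfg,
                            dir = tempfile("sim"), sample_id = "S1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refseq <- ref$sequence
  rl <- cfg$read_len
  out <- with_seed(cfg$seed, {
    haps <- list(build_haplotype(ref, hap1), build_haplotype(ref, hap2))
    recs <- list()
    for (h in seq_along(haps)) {
      hp <- haps[[h]]
      hlen <- length(hp$chars)
      n_pairs <- round((cfg$depth / 2) * hlen / (2 * rl))
      flen <- pmin(pmax(round(stats::rnorm(n_pairs, cfg$insert_mean,
                                           cfg$insert_sd)), rl), hlen)
      fstart <- floor(stats::runif(n_pairs) * (hlen - flen + 1))
      if (cfg$gc_bias != 0) {
        gcc <- c(0, cumsum(hp$chars %in% c("G", "C")))
        gc <- (gcc[fstart + flen + 1L] - gcc[fstart + 1L]) / flen
        w <- pmax(0.05, 1 + cfg$gc_bias * (gc - 0.5) * 10)
        keep <- stats::runif(n_pairs) < w / max(w)
        flen <- flen[keep]; fstart <- fstart[keep]
        n_pairs <- length(flen)
      }
      s1 <- fstart
      s2 <- fstart + flen - rl
      qname <- sprintf("%s_h%d_f%d", sample_id, h, seq_len(n_pairs))
      recs[[h]] <- data.frame(
        qname = rep(qname, 2L),
        flag = rep(c(99L, 147L), each = n_pairs),
        start = c(s1, s2), stringsAsFactors = FALSE)
      recs[[h]]$hap <- h
      recs[[h]]$seq <- substring(hp$seq, recs[[h]]$start + 1L,
                                 recs[[h]]$start + rl)
    }
    reads <- rbind(recs[[1]], recs[[2]])
    n <- nrow(reads)

    ## sequencing errors
    if (cfg$error_rate > 0) {
      nerr <- stats::rbinom(n, rl, cfg$error_rate)
      ei <- rep(which(nerr > 0), nerr[nerr > 0])
      if (length(ei)) {
        ep <- sample.int(rl, length(ei), replace = TRUE)
        cur <- substr(reads$seq[ei], ep, ep)
        new <- other_base(cur)
        for (k in seq_along(ei))
          substr(reads$seq[ei[k]], ep[k], ep[k]) <- new[k]
      }
    }

    ## placement
    gene <- ref$model$gene; ps <- ref$model$pseudogene
    pos <- integer(n); mapq <- integer(n); cigar <- character(n)
    drop <- logical(n)
    simple_cig <- paste0(rl, "M")
    for (h in 1:2) {
      hp <- haps[[h]]
      idx <- which(reads$hap == h)
      rpv <- hp$refpos
      d <- diff(rpv)
      brk <- is.na(d) | d != 1L
      runid <- cumsum(c(1L, brk))
      st <- reads$start[idx]
      contig_ok <- runid[st + 1L] == runid[st + rl] & !is.na(rpv[st + 1L])
      ci <- idx[contig_ok]
      rp0 <- rpv[reads$start[ci] + 1L]
      pos[ci] <- rp0; cigar[ci] <- simple_cig; mapq[ci] <- 60L
      ## ambiguity resolution for reads fully inside a paralog
      ing <- rp0 >= gene$start & (rp0 + rl) <= gene$end
      inp <- rp0 >= ps$start & (rp0 + rl) <= ps$end
      alt <- rep(NA_integer_, length(rp0))
      a0 <- ref$g2p[rp0[ing] + 1L]; a1 <- ref$g2p[rp0[ing] + rl]
      alt[ing] <- ifelse(!is.na(a0) & !is.na(a1) & a1 - a0 == rl - 1L,
                         a0, NA_integer_)
      b0 <- ref$p2g[rp0[inp] + 1L]; b1 <- ref$p2g[rp0[inp] + rl]
      alt[inp] <- ifelse(!is.na(b0) & !is.na(b1) & b1 - b0 == rl - 1L,
                         b0, NA_integer_)
      amb <- which(!is.na(alt))
      if (length(amb)) {
        ai <- ci[amb]
        m_nat <- vapply(seq_along(ai), function(k)
          str_mismatch(reads$seq[ai[k]],
                       substr(refseq, rp0[amb[k]] + 1L, rp0[amb[k]] + rl)),
          0L)
        m_alt <- vapply(seq_along(ai), function(k)
          str_mismatch(reads$seq[ai[k]],
                       substr(refseq, alt[amb[k]] + 1L, alt[amb[k]] + rl)),
          0L)
        take_alt <- m_alt < m_nat
        pos[ai[take_alt]] <- alt[amb[take_alt]]
        tie <- m_alt == m_nat
        if (any(tie)) {
          ti <- ai[tie]
          gene_side <- ifelse(rp0[amb[tie]] >= gene$start &
                                rp0[amb[tie]] < gene$end,
                              rp0[amb[tie]], alt[amb[tie]])
          pos[ti] <- gene_side
          mapq[ti] <- 0L
        }
      }
      ## junction / insert-spanning reads
      for (j in idx[!contig_ok]) {
        rp <- rpv[(reads$start[j] + 1L):(reads$start[j] + rl)]
        pl <- place_junction_read(rp, reads$seq[j], ref, refseq, rl)
        if (is.null(pl)) drop[j] <- TRUE
        else { pos[j] <- pl$pos; cigar[j] <- pl$cigar; mapq[j] <- pl$mapq }
      }
    }
    reads$pos <- pos; reads$mapq <- mapq; reads$cigar <- cigar
    reads <- reads[!drop, , drop = FALSE]

    ## SAM -> sorted indexed BAM
    qual <- strrep("F", rl)
    sam <- file.path(dir, paste0(sample_id, ".sam"))
    con <- file(sam, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 paste0("@SQ\tSN:", ref$contig, "\tLN:", nchar(refseq))),
               con)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s",
                       reads$qname, reads$flag, ref$contig, reads$pos + 1L,
                       reads$mapq, reads$cigar, reads$pos + 1L, reads$seq,
                       qual), con)
    close(con)
    bam <- Rsamtools::asBam(sam, file.path(dir, sample_id),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    bam
  })

  truth <- sample_truth(ref, list(hap1, hap2))
  truth$sample_id <- sample_id
  jsonlite::write_json(truth, file.path(dir, paste0(sample_id,
                                                    ".truth.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(bam = out, truth = truth, sample_id = sample_id)
}

## ground truth implied by the allele specifications
sample_truth <- function(ref, hapspecs) {
  m <- ref$model
  ph <- phasing_sites(m)
  cn_unique <- 2L
  breakpoints <- list()
  variants <- list()
  decoys <- character(0)
  for (specs in hapspecs) {
    for (sp in specs) {
      if (sp$kind == "CNL") {
        cn_unique <- cn_unique - 1L
        path <- interval_contains_pos(m$coding_region, sp$breakpoint)
        psites <- ph$site_id[ph$gene_pos >= sp$breakpoint]
        lab <- match_recombinant(m, psites)
        breakpoints <- c(breakpoints,
                         list(list(kind = "CNL", gene_pos = sp$breakpoint,
                                   pathogenic = path)))
        if (length(psites))
          variants <- c(variants, list(list(label = lab, genotype = "HET",
                                            mechanism = "CNL")))
      } else if (sp$kind == "CNG") {
        cn_unique <- cn_unique + sp$extra_copies
        breakpoints <- c(breakpoints,
                         list(list(kind = "CNG", gene_pos = sp$breakpoint,
                                   pathogenic = FALSE)))
      } else if (sp$kind == "SNV") {
        variants <- c(variants, list(list(label = sp$label,
                                          genotype = "HET",
                                          mechanism = "SNV")))
      } else if (sp$kind == "CONVERSION") {
        psites <- ph$site_id[ph$site_id %in% sp$from_site:sp$to_site]
        lab <- match_recombinant(m, psites)
        variants <- c(variants, list(list(label = lab, genotype = "HET",
                                          mechanism = "CONVERSION")))
      } else if (sp$kind %in% c("REVERSE_SNV", "REVERSE_INDEL")) {
        decoys <- c(decoys, sp$kind)
      }
    }
  }
  ## merge duplicate labels into HOM
  if (length(variants)) {
    labs <- vapply(variants, `[[`, "", "label")
    dup <- duplicated(labs)
    if (any(dup)) {
      for (lb in unique(labs[dup])) {
        first <- which(labs == lb)[1]
        variants[[first]]$genotype <- "HOM"
      }
      variants <- variants[!dup]
    }
  }
  cls <- if (cn_unique <= 1L) "CNL" else if (cn_unique == 2L) "NONE"
         else "CNG"
  list(cn_unique = cn_unique, cnv_class = cls, breakpoints = breakpoints,
       variants = variants, decoys = decoys)
}

## exact-match of a pseudo-site set to a named recombinant
match_recombinant <- function(m, psites) {
  psites <- sort(unique(as.integer(psites)))
  for (lab in names(m$recombinants)) {
    if (identical(sort(m$recombinants[[lab]]), psites)) return(lab)
  }
  paste0("sites:", paste(psites, collapse = "+"))
}

#' Simulate per-position amplicon depth matrices for a sequencing run
#'
#' Emulates a multi-sample amplicon run for the homopolymer depth-anomaly
#' detector: every sample gets its own amplification scale, positions get
#' i.i.d. multiplicative noise, and selected (sample, position) pairs get a
#' multiplicative depth change (e.g. 0.5 for a deletion, 1.5 for an SNV).
#'
#' @param n_samples number of samples in the run (>= 3).
#' @param n_positions number of homopolymer positions tracked.
#' @param anomaly data.frame with columns `sample`, `position`, `factor`, or
#'   NULL for a null run.
#' @param seed integer seed.
#' @param mean_depth mean amplicon depth.
#' @param noise_sd relative per-position noise SD.
#' @return A `run_depth_matrix`: list with `pos_depth` and `flank_depth`
#'   matrices (samples x positions) and the truth data.frame.
#' @export
simulate_run_depths <- function(n_samples, n_positions = 11L, anomaly = NULL,
                                seed, mean_depth = 500, noise_sd = 0.03) {
  if (n_samples < 3L) stop("need >= 3 samples for run statistics")
  with_seed(seed, {
    scale <- mean_depth * exp(stats::rnorm(n_samples, 0, 0.1))
    pos_depth <- matrix(scale, n_samples, n_positions) *
      (1 + stats::rnorm(n_samples * n_positions, 0, noise_sd))
    flank_depth <- matrix(scale, n_samples, n_positions) *
      (1 + stats::rnorm(n_samples * n_positions, 0, noise_sd / sqrt(200)))
    if (!is.null(anomaly)) {
      for (k in seq_len(nrow(anomaly)))
        pos_depth[anomaly$sample[k], anomaly$position[k]] <-
          pos_depth[anomaly$sample[k], anomaly$position[k]] *
          anomaly$factor[k]
    }
    truth <- if (is.null(anomaly)) {
      data.frame(sample = integer(), position = integer(),
                 expected = character())
    } else {
      data.frame(sample = anomaly$sample, position = anomaly$position,
                 expected = ifelse(anomaly$factor < 1, "DELETION", "SNV"))
    }
    structure(list(pos_depth = pos_depth, flank_depth = flank_depth,
                   truth = truth), class = "run_depth_matrix")
  })
}
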