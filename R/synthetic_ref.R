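## Miniature gene/pseudogene reference with planted differentiating sites.
##
## Layout (0-based, default sizes):
##   [0,8000)       left flank (baseline depth windows)
##   [8000,17000)   gene (9 kb, includes a 55 bp gene-only insertion)
##   [17000,27000)  unique inter-paralog spacer (CN-calling region)
##   [27000,35945)  pseudogene (gene copy minus the insertion, with
##                  substitutions at every differentiating site)
##   [35945,43945)  right flank
##
## The last ~2.1 kb of the gene is a high-homology block (~98% identity)
## containing the ten phasing sites; the remainder diverges ~4.6% so that
## the overall paralog identity is ~96%.

mini_layout <- function() {
  list(flank_l = c(0L, 8000L), gene = c(8000L, 17000L),
       spacer = c(17000L, 27000L), pseudo_start = 27000L,
       unique = c(17300L, 26700L), hiblock = c(14800L, 16900L),
       phasing_window = c(15080L, 16290L), coding = c(8150L, 16450L),
       insert = c(15701L, 15756L),   # 55 bp gene-only insertion (site s6)
       phasing_pos = c(15100L, 15201L, 15215L, 15452L, 15540L, 15701L,
                       15798L, 15918L, 16233L, 16262L),
       homopolymers = list(c(9400L, 9406L), c(9650L, 9655L)),
       n409s_pos = 11000L, dupg_pos = 8200L)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

other_base <- function(b) {
  bases <- c("A", "C", "G", "T")
  vapply(b, function(x) sample(setdiff(bases, x), 1L), "")
}

#' Build a miniature gene/pseudogene reference
#'
#' Generates a ~44 kb single-contig reference holding a 9 kb gene, a 10 kb
#' unique spacer, a pseudogene copy and flanking baseline sequence. The
#' pseudogene is the gene with substitutions planted to hit the requested
#' identities (~96% overall, ~98% in the 3' high-homology block) and lacks
#' a 55 bp gene-only insertion. Every substitution is recorded as a
#' differentiating site; ten clustered sites inside the high-homology block
#' (inter-site gaps 14-315 bp) form the phasing set, five of which carry the
#' named target variants (c.1263del55, p.D448H, p.L483P, p.A495P, p.Val499=).
#'
#' @param seed integer seed; the same seed reproduces the reference and model
#'   exactly.
#' @param identity_overall,identity_homology target gene/pseudogene sequence
#'   identities (fractions in (0.9, 1)).
#' @return An object of class `mini_reference`: list with `sequence`
#'   (character scalar), `contig`, `model` (a [paralog_model()]), `g2p`/`p2g`
#'   (per-base homology maps), `insert`, and realized identity stats.
#' @export
build_mini_reference <- function(seed, identity_overall = 0.96,
                                 identity_homology = 0.98) {
  if (identity_overall <= 0.9 || identity_overall >= 1 ||
      identity_homology <= 0.9 || identity_homology >= 1)
    stop("identity parameters must lie in (0.9, 1)")
  if (identity_homology < identity_overall)
    stop("homology-block identity cannot be below overall identity")
  L <- mini_layout()
  gene_len <- L$gene[2] - L$gene[1]
  blk_len <- L$hiblock[2] - L$hiblock[1]
  n_block <- round(blk_len * (1 - identity_homology))
  n_total <- round(gene_len * (1 - identity_overall))
  if (n_block < 11L || n_total <= n_block)
    stop("unreachable identity target: too few differentiating sites")
  n_nonblock <- n_total - n_block
  n_block_bg <- n_block - 10L   # background block sites outside phasing set

  with_seed(seed, {
    total_len <- L$spacer[2] + (gene_len - 55L) + 8000L
    ## blockwise GC structure (real genomes vary ~35-65% across kb-scale
    ## windows); required for the GC-bias machinery to be exercised
    block <- 800L
    n_blocks <- ceiling(total_len / block)
    gc_block <- stats::runif(n_blocks, 0.35, 0.65)
    gc_pos <- rep(gc_block, each = block)[seq_len(total_len)]
    u <- stats::runif(total_len)
    chars <- ifelse(u < gc_pos / 2, "G",
             ifelse(u < gc_pos, "C",
             ifelse(u < gc_pos + (1 - gc_pos) / 2, "A", "T")))
    ## deterministic anchors used by variants/homopolymers
    for (hp in L$homopolymers) chars[(hp[1] + 1):hp[2]] <- "A"
    chars[L$dupg_pos:(L$dupg_pos + 2)] <- "G"  # GG run for the dup variant

    insert <- L$insert
    post_ins <- chars[insert[2] + 1L]
    if (chars[insert[1] + 1L] == post_ins)
      chars[insert[1] + 1L] <- other_base(post_ins)

    ## positions barred from background substitutions
    excl <- c(L$n409s_pos + (-2:2), L$dupg_pos + (-2:4),
              insert[1]:(insert[2] + 2L),
              unlist(lapply(L$homopolymers, function(h) h[1]:(h[2] + 1L))))
    nb_cand <- setdiff(c(L$gene[1]:(L$hiblock[1] - 1L),
                         L$hiblock[2]:(L$gene[2] - 1L)), excl)
    blk_cand <- setdiff(c(L$hiblock[1]:(L$phasing_window[1] - 1L),
                          L$phasing_window[2]:(L$hiblock[2] - 1L)), excl)
    sub_pos <- sort(c(sample(nb_cand, n_nonblock),
                      sample(blk_cand, n_block_bg)))

    site_pos <- sort(c(sub_pos, L$phasing_pos))
    is_indel <- site_pos == insert[1]
    gene_base <- chars[site_pos + 1L]
    pseudo_base <- other_base(gene_base)
    pseudo_base[is_indel] <- post_ins
    if (gene_base[is_indel] == pseudo_base[is_indel])
      stop("internal: indel site alleles collide")

    ## pseudogene sequence: gene copy minus insertion, pseudo bases planted
    gene_chars <- chars[(L$gene[1] + 1L):L$gene[2]]
    keep <- setdiff(seq_len(gene_len),
                    (insert[1] - L$gene[1] + 1L):(insert[2] - L$gene[1]))
    ps_chars <- gene_chars[keep]
    off_pre <- L$pseudo_start - L$gene[1]
    off_post <- off_pre - 55L
    pseudo_pos <- site_pos + ifelse(site_pos < insert[1], off_pre, off_post)
    pseudo_pos[is_indel] <- insert[2] + off_post
    ps_chars[pseudo_pos - L$pseudo_start + 1L] <- pseudo_base
    pseudo_len <- length(ps_chars)
    chars <- c(chars[1:L$spacer[2]], ps_chars,
               chars[(L$spacer[2] + pseudo_len + 1L):total_len])

    ## per-base homology maps (reference coordinates, 0-based)
    g2p <- rep(NA_integer_, total_len)
    gpos <- L$gene[1]:(L$gene[2] - 1L)
    g2p[gpos + 1L] <- ifelse(gpos < insert[1], gpos + off_pre,
                      ifelse(gpos >= insert[2], gpos + off_post,
                             NA_integer_))
    p2g <- rep(NA_integer_, total_len)
    ok <- !is.na(g2p)
    p2g[g2p[ok] + 1L] <- which(ok) - 1L

    contig <- "mini"
    n409s_ref <- chars[L$n409s_pos + 1L]
    variants <- data.frame(
      label = c("p.N409S", "c.84dupG", "c.1263del55", "p.D448H", "p.L483P",
                "p.A495P", "p.Val499="),
      gene_pos = c(L$n409s_pos, L$dupg_pos, L$phasing_pos[6:10]),
      ref_allele = c(n409s_ref, "G",
                     gene_base[match(L$phasing_pos[6:10], site_pos)]),
      alt_allele = c(other_base(n409s_ref), "GG",
                     pseudo_base[match(L$phasing_pos[6:10], site_pos)]),
      gbap1_like = c(FALSE, FALSE, rep(TRUE, 5)),
      in_homology_region = c(FALSE, FALSE, rep(TRUE, 5)),
      severity = c("mild", "severe", "severe", "severe", "severe",
                   "unknown", "unknown"),
      stringsAsFactors = FALSE)

    sites <- data.frame(
      site_id = seq_along(site_pos),
      gene_pos = site_pos, pseudo_pos = pseudo_pos,
      gene_base = gene_base, pseudo_base = pseudo_base,
      in_phasing_set = site_pos %in% L$phasing_pos,
      is_sentinel = site_pos >= L$phasing_window[1],
      reliable = TRUE,
      is_indel = is_indel,
      indel_len = ifelse(is_indel, 55L, 0L),
      stringsAsFactors = FALSE)
    phasing_ids <- sites$site_id[sites$in_phasing_set]
    recs <- list("p.L483P" = phasing_ids[8],
                 "p.D448H" = phasing_ids[7],
                 "c.1263del55" = phasing_ids[6],
                 "RecNciI" = phasing_ids[8:10],
                 "RecTL" = phasing_ids[7:10],
                 "c.1263del+RecTL" = phasing_ids[6:10])

    gi <- function(v) genomic_interval(contig, v[1], v[2])
    model <- paralog_model(
      contig = contig,
      gene = gi(L$gene),
      pseudogene = genomic_interval(contig, L$pseudo_start,
                                    L$pseudo_start + pseudo_len),
      unique_cn_region = gi(L$unique),
      homology_region = gi(L$phasing_window),
      coding_region = gi(L$coding),
      sites = sites, variants = variants, recombinants = recs,
      baseline_regions = list(genomic_interval(contig, 200L, 7800L),
                              genomic_interval(contig,
                                               L$pseudo_start + pseudo_len +
                                                 200L,
                                               length(chars) - 200L)),
      homopolymers = lapply(L$homopolymers, gi))

    n_diff <- length(site_pos)
    n_blk <- sum(site_pos >= L$hiblock[1] & site_pos < L$hiblock[2])
    structure(list(
      sequence = paste(chars, collapse = ""), contig = contig,
      model = model, g2p = g2p, p2g = p2g,
      insert = list(start = insert[1], end = insert[2], len = 55L,
                    seq = paste(chars[(insert[1] + 1L):insert[2]],
                                collapse = "")),
      layout = L,
      identity_overall = 1 - n_diff / gene_len,
      identity_homology = 1 - n_blk / blk_len),
      class = "mini_reference")
  })
}

#' Write the mini reference as FASTA
#'
#' @param ref a `mini_reference`.
#' @param path output FASTA path (an `.fai` index is created alongside).
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$contig
  Biostrings::writeXStringSet(x, path)
  Rsamtools::indexFa(path)
  invisible(path)
}
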