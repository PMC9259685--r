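## Read-backed phasing of the exon 9-11 differentiating sites.
##
## Every fragment (read pair) is typed as G (gene base) or P (pseudogene
## base) at each phasing site it covers, pooling the gene and pseudogene
## positions exactly as in the site-CN counts, so phasing never depends on
## which paralog the aligner chose. Haplotypes over the ten sites are
## assembled greedily from fragment linkage, given integer copy numbers
## summing to the combined CN, and the one-vs-two wild-type-copy scenario
## comparison decides carrier status. Hybrid haplotypes whose 5'-most site
## carries the pseudogene base are treated as (possibly back-converted)
## pseudogene copies: this is what defeats the reverse-conversion decoys
## that drive false positives in alignment-based pipelines.

#' Extract phasing fragments
#'
#' @param bam path to an indexed BAM or a [load_reads()] data.frame.
#' @param model a [paralog_model()].
#' @param min_base_quality minimum base quality (default 13).
#' @return A `haplotype_fragments` object: character matrix (fragments x
#'   phasing sites) with entries "G", "P" or NA. Mate pairs are merged by
#'   read name; a mate conflict at a site drops that site from the
#'   fragment.
#' @export
extract_fragments <- function(bam, model, min_base_quality = 13L) {
  reads <- if (is.data.frame(bam)) bam else load_reads(bam)
  ph <- phasing_sites(model)
  calls <- site_allele_calls(reads, model, min_base_quality, sites = ph)
  calls <- calls[calls$allele %in% c("G", "P"), , drop = FALSE]
  qn <- unique(calls$qname)
  mat <- matrix(NA_character_, length(qn), nrow(ph),
                dimnames = list(qn, ph$site_id))
  if (nrow(calls))
    mat[cbind(match(calls$qname, qn),
              match(calls$site_id, ph$site_id))] <- calls$allele
  mat <- mat[rowSums(!is.na(mat)) > 0L, , drop = FALSE]
  structure(mat, class = "haplotype_fragments")
}

## all contiguous P-intervals on a G background and G-intervals on a P
## background over S ordered sites (canonical all-G/all-P excluded)
template_haplotypes <- function(S) {
  out <- list()
  for (a in seq_len(S)) {
    for (b in a:S) {
      h <- rep("G", S); h[a:b] <- "P"
      out[[length(out) + 1L]] <- h
      h2 <- rep("P", S); h2[a:b] <- "G"
      out[[length(out) + 1L]] <- h2
    }
  }
  out[!vapply(out, function(h) all(h == "G") || all(h == "P"), TRUE)]
}

frag_consistent <- function(mat, hap) {
  ## fragments whose every typed site agrees with the (partial) haplotype
  S <- length(hap)
  ok <- rep(TRUE, nrow(mat))
  for (s in seq_len(S)) {
    if (is.na(hap[s])) next
    ok <- ok & (is.na(mat[, s]) | mat[, s] == hap[s])
  }
  ok
}

#' Assemble haplotypes over the phasing sites
#'
#' Deterministic three-stage assembly. (1) The canonical strings (all
#' gene bases, all pseudogene bases) are kept when at least
#' `min_hap_support` unexplained fragments are consistent with them.
#' (2) Recombination templates — every contiguous pseudogene-base
#' interval on a gene background (conversions, fusion suffixes, single
#' GBAP1-like variants) and every gene-base interval on a pseudogene
#' background (duplication hybrids, reverse-conversion decoys) — are
#' scored by the gain in the fragment mixture likelihood and accepted
#' greedily with a per-haplotype penalty and a pair lookahead (a
#' compound heterozygote's two single-site haplotypes must be able to
#' beat the interval chimera between them). (3) Residual fragments are
#' peeled by seeded chain extension with majority linkage votes (two
#' voting fragments required, ties broken toward the gene base, sites
#' without linkage imputed to the gene base and excluded from origin
#' assignment). Assembled strings are polished — a site resting on fewer
#' than two linked consistent fragments is re-voted — deduplicated, and
#' pruned: a haplotype without at least `min_unique_support` uniquely
#' consistent fragments is a shared-prefix phantom and is removed.
#'
#' @param fragments a `haplotype_fragments` matrix.
#' @param model a [paralog_model()].
#' @param max_haplotypes cap, normally the combined copy number.
#' @param min_hap_support minimum supporting fragments per haplotype
#'   (default 3).
#' @param min_unique_support minimum uniquely-explained fragments for a
#'   haplotype to survive pruning (default 2).
#' @return data.frame `allele_string`, `support`, plus attribute
#'   `ambiguous` (any tie was broken) — copy numbers are added by
#'   [call_haplotype_cn()].
#' @export
assemble_haplotypes <- function(fragments, model, max_haplotypes = 10L,
                                min_hap_support = 3L,
                                min_unique_support = 2L) {
  mat <- unclass(fragments)
  S <- ncol(mat)
  unexplained <- rep(TRUE, nrow(mat))
  haps <- character(0)
  masks <- character(0)
  ambiguous <- FALSE

  explain <- function(hapstr, mask) {
    cons <- frag_consistent(mat, strsplit(hapstr, "")[[1]])
    unexplained <<- unexplained & !cons
    haps <<- c(haps, hapstr)
    masks <<- c(masks, mask)
  }

  ## canonical haplotypes first: assembling the pure gene and pseudogene
  ## strings before any hybrid keeps chained extension from absorbing
  ## their fragments into chimeras
  for (cand in c(wt_string(S), strrep("P", S))) {
    if (length(haps) >= max_haplotypes) break
    cons <- frag_consistent(mat, strsplit(cand, "")[[1]]) & unexplained
    if (sum(cons) >= min_hap_support) explain(cand, strrep(".", S))
  }

  ## recombination produces contiguous patterns over the ordered sites:
  ## P-intervals (conversions, incl. single GBAP1-like variants and
  ## fusion suffixes) and their reverse counterparts (back-converted
  ## pseudogene copies, duplication-hybrid prefixes). Score every such
  ## template against the unexplained fragments and accept greedily —
  ## fragment-chaining alone cannot bridge sites further apart than a
  ## fragment, template matching can.
  templates <- template_haplotypes(S)
  tpl_ll <- function(cm) {
    ## best composition likelihood for the given consistency matrix;
    ## zero copies allowed so a phantom canonical cannot strangle the
    ## capacity needed by genuine variant haplotypes
    H <- ncol(cm)
    if (H == 0L) return(nrow(mat) * log(0.02))
    comps <- compositions(as.integer(max(max_haplotypes, H)), H,
                          min1 = FALSE)
    max(vapply(comps, mixture_loglik, 0, cm = cm,
               cn_total = max(max_haplotypes, H)))
  }
  repeat {
    if (sum(unexplained) < min_hap_support ||
        length(haps) >= max_haplotypes) break
    sub <- mat[unexplained, , drop = FALSE]
    multi <- rowSums(!is.na(sub)) >= 2L
    sup <- vapply(templates, function(h) sum(frag_consistent(sub, h)), 0L)
    sup_multi <- vapply(templates, function(h)
      sum(frag_consistent(sub, h) & multi), 0L)
    short <- which(sup >= min_hap_support & sup_multi >= 2L)
    if (!length(short)) break
    base_cm <- if (length(haps)) {
      m0 <- vapply(haps, function(h)
        frag_consistent(mat, strsplit(h, "")[[1]]), logical(nrow(mat)))
      if (is.null(dim(m0))) m0 <- matrix(m0, nrow = nrow(mat))
      m0
    } else matrix(FALSE, nrow(mat), 0L)
    ll0 <- tpl_ll(base_cm)
    cons_cache <- lapply(short, function(ti)
      frag_consistent(mat, templates[[ti]]))
    gains <- vapply(seq_along(short), function(k)
      tpl_ll(cbind(base_cm, cons_cache[[k]])) - ll0, 0)
    ## penalized scores with pair lookahead: a compound heterozygote's two
    ## single-site haplotypes jointly beat the interval chimera that
    ## single-step greedy would pick
    per_hap_penalty <- 5
    best_single <- max(gains) - per_hap_penalty
    best_pair <- -Inf; pair_idx <- NULL
    if (length(short) > 1L && length(haps) + 2L <= max_haplotypes) {
      for (a in seq_along(short)[-length(short)]) {
        for (b in (a + 1L):length(short)) {
          g <- tpl_ll(cbind(base_cm, cons_cache[[a]], cons_cache[[b]])) -
            ll0 - 2 * per_hap_penalty
          if (g > best_pair) { best_pair <- g; pair_idx <- c(a, b) }
        }
      }
    }
    if (max(best_single, best_pair) < 0) break
    if (best_pair > best_single + 1e-9) {
      for (k in pair_idx)
        explain(paste(templates[[short[k]]], collapse = ""),
                strrep(".", S))
      templates <- templates[-short[pair_idx]]
    } else {
      cand <- which(gains >= max(gains) - 1e-9)
      if (length(cand) > 1L) {  # toward the gene: fewest pseudo alleles
        np <- vapply(templates[short[cand]], function(h) sum(h == "P"), 0L)
        cand <- cand[np == min(np)]
        strs <- vapply(templates[short[cand]], paste, "", collapse = "")
        cand <- cand[order(strs)]
      }
      explain(paste(templates[[short[cand[1L]]]], collapse = ""),
              strrep(".", S))
      templates <- templates[-short[cand[1L]]]
    }
  }

  while (sum(unexplained) >= min_hap_support &&
         length(haps) < max_haplotypes) {
    sub <- mat[unexplained, , drop = FALSE]
    sig <- apply(sub, 1L, function(r) paste(ifelse(is.na(r), ".", r),
                                            collapse = ""))
    tab <- sort(table(sig), decreasing = TRUE)
    ## a signature observed once cannot seed: a single fragment is
    ## indistinguishable from a sequencing-error chimera
    if (tab[1L] < 2L) break
    cands <- names(tab)[tab == tab[1L]]
    if (length(cands) > 1L) {
      ## prefer more typed sites, then more gene bases, then lexicographic
      ntyped <- nchar(gsub("\\.", "", cands))
      cands <- cands[ntyped == max(ntyped)]
      ng <- vapply(strsplit(cands, ""), function(x) sum(x == "G"), 0L)
      cands <- sort(cands[ng == max(ng)])
    }
    hap <- strsplit(cands[1L], "")[[1]]
    hap[hap == "."] <- NA_character_
    mask <- ifelse(is.na(hap), "i", ".")
    while (anyNA(hap)) {
      assigned <- which(!is.na(hap))
      frontier <- which(is.na(hap) &
                          (c(FALSE, !is.na(hap[-S])) |
                             c(!is.na(hap[-1L]), FALSE)))
      if (!length(frontier)) frontier <- which(is.na(hap))[1L]
      ## primary votes come from unexplained fragments consistent with
      ## the partial haplotype and linked to an assigned site; borrowing
      ## explained fragments here would let an abundant haplotype hijack
      ## the extension
      cons <- frag_consistent(sub, hap)
      linked <- rowSums(!is.na(sub[, assigned, drop = FALSE])) > 0L
      ## a link is distinctive when it runs through a site carrying the
      ## partial haplotype's minority allele — linkage through shared
      ## background sites cannot tell copies apart and invites chimeras
      n_g <- sum(hap[assigned] == "G")
      minority <- if (n_g >= length(assigned) - n_g) "P" else "G"
      strong_sites <- assigned[hap[assigned] == minority]
      strong <- if (length(strong_sites)) {
        rowSums(!is.na(sub[, strong_sites, drop = FALSE])) > 0L
      } else linked
      votes <- lapply(frontier, function(s) {
        v <- sub[cons & strong & !is.na(sub[, s]), s]
        if (!length(v)) v <- sub[cons & linked & !is.na(sub[, s]), s]
        table(factor(v, levels = c("G", "P")))
      })
      nv <- vapply(votes, sum, 0L)
      ## a lone voting fragment may be a sequencing error: require two
      if (any(nv >= 2L)) {
        j <- which.max(nv)
        s <- frontier[j]; vt <- votes[[j]]
        if (vt["G"] == vt["P"]) { hap[s] <- "G"; ambiguous <- TRUE }
        else hap[s] <- names(vt)[which.max(vt)]
        mask[s] <- "."
        next
      }
      ## no unexplained linkage anywhere on the frontier: consult all
      ## consistent linked fragments (including explained ones) and take
      ## their verdict only when unanimous — absence of any conflicting
      ## fragment is evidence (e.g. a fusion suffix continues in P when
      ## no P+G-linking fragment exists)
      cons_all <- frag_consistent(mat, hap)
      linked_all <- rowSums(!is.na(mat[, assigned, drop = FALSE])) > 0L
      votes2 <- lapply(frontier, function(s) {
        v <- mat[cons_all & linked_all & !is.na(mat[, s]), s]
        table(factor(v, levels = c("G", "P")))
      })
      nv2 <- vapply(votes2, sum, 0L)
      j <- which.max(nv2)
      s <- frontier[j]; vt <- votes2[[j]]
      if (sum(vt) >= 2L && min(vt) == 0L) {
        hap[s] <- names(vt)[which.max(vt)]
        mask[s] <- "l"
      } else {
        ## contested or no evidence: default to the gene base; the site
        ## is imputed and carries no weight for origin assignment
        hap[s] <- "G"
        mask[s] <- "i"
        if (sum(vt) > 0L) ambiguous <- TRUE
      }
    }
    hapstr <- paste(hap, collapse = "")
    if (sum(frag_consistent(sub, hap)) < min_hap_support) break
    explain(hapstr, paste(mask, collapse = ""))
  }

  pol <- polish_haplotypes(haps, mat)
  dup <- duplicated(pol)
  haps <- pol[!dup]; masks <- masks[!dup]
  ## prune phantoms: keep haplotypes with enough uniquely-consistent frags
  if (length(haps) > 1L) {
    cm <- vapply(haps, function(h)
      frag_consistent(mat, strsplit(h, "")[[1]]), logical(nrow(mat)))
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = nrow(mat))
    nuniq <- colSums(cm & rowSums(cm) == 1L)
    keep <- nuniq >= min_unique_support
    if (!any(keep)) keep <- nuniq == max(nuniq)
    haps <- haps[keep]; masks <- masks[keep]
  }
  support <- vapply(haps, function(h)
    sum(frag_consistent(mat, strsplit(h, "")[[1]])), 0L)
  out <- data.frame(allele_string = haps, support = as.integer(support),
                    imputed = masks, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "ambiguous") <- ambiguous
  out
}

## re-vote haplotype sites whose assignment rests on a single fragment;
## removes lone sequencing-error alleles picked up during seeding
polish_haplotypes <- function(haps, mat) {
  S <- ncol(mat)
  multi <- rowSums(!is.na(mat)) >= 2L  # linked fragments only
  vapply(haps, function(hs) {
    hap <- strsplit(hs, "")[[1]]
    cons <- frag_consistent(mat, hap)
    for (s in seq_len(S)) {
      n_agree <- sum(cons & multi & !is.na(mat[, s]))
      if (n_agree >= 2L) next
      hap_except <- hap; hap_except[s] <- NA_character_
      voters <- frag_consistent(mat, hap_except) & !is.na(mat[, s])
      v <- table(factor(mat[voters, s], levels = c("G", "P")))
      if (sum(v) == 0L) next
      alt <- names(v)[which.max(v)]
      if (v["G"] == v["P"]) alt <- "G"
      if (alt != hap[s]) {
        hap[s] <- alt
        cons <- frag_consistent(mat, hap)
      }
    }
    paste(hap, collapse = "")
  }, "", USE.NAMES = FALSE)
}

## fragment-by-haplotype consistency indicator matrix
consistency_matrix <- function(fragments, haplotypes) {
  mat <- unclass(fragments)
  H <- nrow(haplotypes)
  cm <- matrix(FALSE, nrow(mat), H)
  for (h in seq_len(H)) {
    hap <- strsplit(haplotypes$allele_string[h], "")[[1]]
    cm[, h] <- frag_consistent(mat, hap)
  }
  cm[rowSums(cm) > 0L, , drop = FALSE]  # drop fragments explained by none
}

compositions <- function(n, k, min1 = TRUE) {
  ## all integer vectors length k, entries >= 1 (or >= 0), summing to n
  lo <- if (min1) 1L else 0L
  if (k == 0L) return(if (n == 0L) list(integer(0)) else list())
  if (k == 1L) return(if (n >= lo) list(n) else list())
  out <- list()
  for (v in lo:(n - lo * (k - 1L))) {
    rest <- compositions(n - v, k - 1L, min1)
    out <- c(out, lapply(rest, function(r) c(v, r)))
  }
  out
}

mixture_loglik <- function(cm, cn, cn_total, err_floor = 0.02) {
  ## sum over fragments of log(share of copies consistent with it); the
  ## floor absorbs rare error fragments so they cannot veto a composition
  share <- as.numeric(cm %*% cn) / cn_total
  sum(log(pmax(share, err_floor)))
}

#' Assign integer copy numbers to haplotypes
#'
#' Maximizes a mixture likelihood in which each phasing fragment arises
#' from one of the physical copies: a composition `(c_1..c_H)` with
#' `sum(c_h) = cn_total` scores `sum_f log(sum_{h consistent with f} c_h /
#' cn_total)`. All compositions are enumerated (H <= cn_total <= 10).
#' Fragments informative for a single haplotype make this the multinomial
#' likelihood on their counts.
#'
#' @param haplotypes output of [assemble_haplotypes()].
#' @param fragments the `haplotype_fragments` used to assemble them.
#' @param cn_total combined gene+pseudogene copy number.
#' @return `haplotypes` with a `cn` column, attribute `loglik`.
#' @export
call_haplotype_cn <- function(haplotypes, fragments, cn_total) {
  H <- nrow(haplotypes)
  if (H == 0L) return(cbind(haplotypes, cn = integer(0)))
  if (H > cn_total)
    stop("more haplotypes than copies: increase min_hap_support?")
  cm <- consistency_matrix(fragments, haplotypes)
  if (H == 1L) {
    haplotypes$cn <- as.integer(cn_total)
    attr(haplotypes, "loglik") <- 0
    return(haplotypes)
  }
  ## every surviving haplotype gets >= 1 copy: phantoms were already
  ## pruned during assembly on unique fragment support
  comps <- compositions(as.integer(cn_total), H, min1 = TRUE)
  ll <- vapply(comps, mixture_loglik, 0, cm = cm, cn_total = cn_total)
  best <- which.max(ll)
  haplotypes$cn <- as.integer(comps[[best]])
  attr(haplotypes, "loglik") <- ll[best]
  attr(haplotypes, "consistency") <- cm
  haplotypes
}

#' Split duplication-hybrid chimeras
#'
#' Under a copy-number gain, fragment linkage cannot connect the 5' and 3'
#' ends of the phasing window across widely separated sites, so a
#' pseudogene-prefix hybrid copy and a gene variant copy can be assembled
#' as a single string (P-prefix, G-run, then P again). A single crossover
#' cannot produce that shape: such strings are split into the hybrid
#' (P-prefix + G) and the variant (G-prefix + observed remainder).
#'
#' @param haplotypes assembled haplotypes (before CN assignment).
#' @param fragments the `haplotype_fragments`.
#' @param max_haplotypes combined copy number cap.
#' @return The haplotype data.frame, with chimeric rows split.
#' @export
split_hybrid_chimeras <- function(haplotypes, fragments, max_haplotypes) {
  mat <- unclass(fragments)
  out <- haplotypes[0, , drop = FALSE]
  for (h in seq_len(nrow(haplotypes))) {
    al <- strsplit(haplotypes$allele_string[h], "")[[1]]
    mk <- strsplit(haplotypes$imputed[h], "")[[1]]
    S <- length(al)
    run_end <- 0L
    while (run_end < S && al[run_end + 1L] == "P") run_end <- run_end + 1L
    splittable <- run_end >= 1L && mk[1L] != "i" &&
      any(al[-seq_len(run_end)] == "P") &&
      nrow(haplotypes) + 1L <= max_haplotypes
    if (!splittable) {
      out <- rbind(out, haplotypes[h, , drop = FALSE])
      next
    }
    a_al <- c(rep("P", run_end), rep("G", S - run_end))
    b_al <- c(rep("G", run_end), al[(run_end + 1L):S])
    a_mk <- c(mk[seq_len(run_end)], rep("l", S - run_end))
    b_mk <- c(rep("l", run_end), mk[(run_end + 1L):S])
    for (x in list(list(a_al, a_mk), list(b_al, b_mk))) {
      sup <- sum(frag_consistent(mat, x[[1]]))
      out <- rbind(out, data.frame(
        allele_string = paste(x[[1]], collapse = ""),
        support = as.integer(sup),
        imputed = paste(x[[2]], collapse = ""),
        stringsAsFactors = FALSE))
    }
  }
  out[!duplicated(out$allele_string), , drop = FALSE]
}

#' Reconcile phased haplotypes with the per-site gene copy number
#'
#' Fragment linkage cannot always determine a haplotype's allele at every
#' site (pure-P or pure-G fragments are shared between copies), but the
#' pooled per-site gene CN constrains the haplotype set: at every phasing
#' site the copy-weighted number of G alleles must match the estimated
#' gene CN. Sites set by fallback voting or imputation (mask "l"/"i") are
#' flipped when doing so moves the copy-weighted G count toward the
#' site-CN estimate; copy numbers are then re-fitted. Fragment-voted
#' sites (mask ".") are never touched.
#'
#' @param haplotypes_cn CN-annotated haplotypes from
#'   [call_haplotype_cn()].
#' @param fragments the `haplotype_fragments`.
#' @param series a `site_cn_series` (provides `cn_gene` per phasing site).
#' @param model the [paralog_model()].
#' @param cn_total combined copy number.
#' @return The reconciled, re-fitted haplotype data.frame.
#' @export
reconcile_haplotypes <- function(haplotypes_cn, fragments, series, model,
                                 cn_total) {
  ph <- phasing_sites(model)
  idx <- match(ph$site_id, series$site_id)
  target <- series$cn_gene[idx]
  ## only trust confidently-estimated sites as flip targets; site
  ## posteriors are overconfident under fragment clumping, hence 0.99
  target[!is.na(target) & series$posterior[idx] < 0.99] <- NA_integer_
  mat <- unclass(fragments)
  haps <- haplotypes_cn
  for (iter in 1:3) {
    changed <- FALSE
    al <- strsplit(haps$allele_string, "")
    mk <- strsplit(haps$imputed, "")
    cm <- vapply(al, function(a) frag_consistent(mat, a),
                 logical(nrow(mat)))
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = nrow(mat))
    uniq <- cm & rowSums(cm) == 1L
    for (s in seq_len(nrow(ph))) {
      if (is.na(target[s])) next
      for (h in seq_len(nrow(haps))) {
        if (mk[[h]][s] == ".") next
        ## fragments that can only belong to this haplotype and observed
        ## the current allele at the site veto the flip (two or more, so
        ## a lone error fragment cannot freeze a site)
        if (sum(uniq[, h] & !is.na(mat[, s]) &
                  mat[, s] == al[[h]][s]) >= 2L) next
        g_tot <- sum(haps$cn[vapply(al, `[[`, "", s) == "G"])
        flip_to <- if (al[[h]][s] == "G") "P" else "G"
        g_new <- g_tot + (if (flip_to == "G") haps$cn[h] else -haps$cn[h])
        if (abs(g_new - target[s]) < abs(g_tot - target[s])) {
          al[[h]][s] <- flip_to
          mk[[h]][s] <- "s"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
    haps$allele_string <- vapply(al, paste, "", collapse = "")
    haps$imputed <- vapply(mk, paste, "", collapse = "")
    dup <- duplicated(haps$allele_string)
    if (any(dup)) haps <- haps[!dup, , drop = FALSE]
    haps$cn <- NULL
    haps <- call_haplotype_cn(haps, fragments, cn_total)
  }
  haps
}

wt_string <- function(n) strrep("G", n)

## origin from the 5'-most site actually observed for the haplotype:
## gene-origin iff it carries the gene base there. Imputed (data-free)
## sites are skipped — they default to G and must not confer gene origin.
hap_is_gene_origin <- function(allele_string, imputed = NULL) {
  if (is.null(imputed)) imputed <- strrep(".", nchar(allele_string[1]))
  vapply(seq_along(allele_string), function(i) {
    al <- strsplit(allele_string[i], "")[[1]]
    mk <- strsplit(imputed[i], "")[[1]]
    obs <- which(mk != "i")
    if (!length(obs)) return(FALSE)
    al[obs[1L]] == "G"
  }, TRUE)
}

#' Compare the one- vs two-wild-type-copy scenarios
#'
#' Fixes the copy number of the all-gene-base (wild-type) haplotype at 1
#' and at 2, re-optimizing the remaining copy numbers under each
#' hypothesis (profile likelihood), and reports which scenario the
#' fragment data support. One wild-type copy means the sample carries a
#' variant on the other gene copy (HET); absence of any wild-type gene
#' haplotype yields HOM (one distinct variant haplotype) or COMPOUND_HET
#' (more than one, with no haplotype carrying the gene base at every
#' variant site).
#'
#' @param haplotypes_cn output of [call_haplotype_cn()].
#' @param fragments the `haplotype_fragments`.
#' @param cn_total combined copy number.
#' @param tol likelihood-tie tolerance (default 1e-9).
#' @return A `scenario_call`: `wildtype_gba_copies`,
#'   `log_likelihood_ratio` (scenario 1 minus scenario 2), `genotype`
#'   ("WT", "HET", "HOM", "COMPOUND_HET"), `no_call`.
#' @export
compare_scenarios <- function(haplotypes_cn, fragments, cn_total,
                              tol = 1e-9) {
  S <- ncol(unclass(fragments))
  haps <- haplotypes_cn
  res <- function(wt, llr, geno, no_call = FALSE)
    structure(list(wildtype_gba_copies = wt, log_likelihood_ratio = llr,
                   genotype = geno, no_call = no_call),
              class = "scenario_call")
  if (!nrow(haps)) return(res(NA_integer_, NA_real_, NA_character_, TRUE))
  gene_side <- hap_is_gene_origin(haps$allele_string, haps$imputed)
  wt_idx <- which(haps$allele_string == wt_string(S))
  variant_idx <- which(gene_side & haps$allele_string != wt_string(S))

  if (!length(wt_idx)) {
    if (!length(variant_idx))
      return(res(0L, NA_real_, NA_character_, TRUE))
    geno <- if (length(variant_idx) > 1L) "COMPOUND_HET" else "HOM"
    return(res(0L, NA_real_, geno))
  }
  if (nrow(haps) == 1L)   # only the wild-type haplotype present
    return(res(as.integer(cn_total), NA_real_, "WT"))

  cm <- consistency_matrix(fragments, haps)
  prof <- function(wt_cn) {
    others <- setdiff(seq_len(nrow(haps)), wt_idx)
    rem <- cn_total - wt_cn
    if (rem < 0L) return(-Inf)
    comps <- compositions(as.integer(rem), length(others), min1 = FALSE)
    max(vapply(comps, function(cc) {
      cn <- integer(nrow(haps)); cn[wt_idx] <- wt_cn; cn[others] <- cc
      mixture_loglik(cm, cn, cn_total)
    }, 0))
  }
  ll1 <- prof(1L); ll2 <- prof(2L)
  llr <- ll1 - ll2
  if (is.finite(llr) && abs(llr) < tol)
    return(res(NA_integer_, llr, NA_character_, TRUE))
  if (ll2 >= ll1) return(res(2L, llr, "WT"))
  geno <- if (length(variant_idx) >= 1L) "HET" else "WT"
  res(1L, llr, geno)
}

#' Refine CNV breakpoint intervals with phased haplotypes
#'
#' The site-CN changepoint can be displaced by correlated coverage noise;
#' the phased fusion/hybrid haplotype pins the breakpoint down directly
#' (a fusion switches from gene to pseudogene bases at the breakpoint,
#' a duplication hybrid from pseudogene to gene). When such a haplotype
#' places the transition inside the phasing window, the corresponding
#' breakpoint interval is replaced by the bracketing phasing sites.
#'
#' @param breakpoints data.frame from [detect_cn_transitions()].
#' @param haplotypes_cn reconciled, CN-annotated haplotypes.
#' @param cn_call a `copy_number_call`.
#' @param model the [paralog_model()].
#' @return The breakpoint data.frame, possibly with refined intervals.
#' @export
refine_breakpoints <- function(breakpoints, haplotypes_cn, cn_call,
                               model) {
  if (!nrow(haplotypes_cn) || !nrow(breakpoints)) return(breakpoints)
  ph <- phasing_sites(model)
  S <- nrow(ph)
  al <- strsplit(haplotypes_cn$allele_string, "")
  gene_side <- hap_is_gene_origin(haplotypes_cn$allele_string,
                                  haplotypes_cn$imputed)
  set_iv <- function(rows, i_left, i_right) {
    breakpoints$left_site[rows] <<- ph$site_id[i_left]
    breakpoints$right_site[rows] <<- ph$site_id[i_right]
    breakpoints$left_pos[rows] <<- ph$gene_pos[i_left]
    breakpoints$right_pos[rows] <<- ph$gene_pos[i_right]
  }
  if (cn_call$cnv_class == "CNL") {
    rows <- which(breakpoints$kind == "CNL")
    for (h in which(gene_side)) {
      a <- al[[h]]
      i0 <- which(a == "P")
      if (!length(i0)) next
      i0 <- min(i0)
      if (i0 > 1L && all(a[i0:S] == "P") && length(rows)) {
        set_iv(rows[1L], i0 - 1L, i0)
        break
      }
    }
  } else if (cn_call$cnv_class == "CNG") {
    rows <- which(breakpoints$kind == "CNG")
    for (h in which(!gene_side)) {
      a <- al[[h]]
      j0 <- which(a == "G")
      if (!length(j0)) next
      j0 <- min(j0)
      if (j0 > 1L && all(a[seq_len(j0 - 1L)] == "P") &&
          all(a[j0:S] == "G") && length(rows)) {
        set_iv(rows[1L], j0 - 1L, j0)
        break
      }
    }
  }
  breakpoints
}

## is the P-site set a contiguous 3' suffix of the phasing sites?
is_3prime_suffix <- function(psites, phasing_ids) {
  if (!length(psites)) return(FALSE)
  n <- length(phasing_ids)
  k <- length(psites)
  identical(sort(psites), phasing_ids[(n - k + 1L):n])
}

#' Map phased haplotypes to named recombinants and mechanisms
#'
#' Every non-wild-type gene-origin haplotype is matched to the named
#' recombinant whose pseudogene-site set it carries exactly (e.g. RecNciI
#' for p.L483P + p.A495P + p.Val499=); with a CNL copy-number class and a
#' breakpoint 5' of those sites the mechanism is a fusion (CNL), with no
#' CNV it is a gene conversion (two or more sites) or a point variant
#' (one site). CNGs are reported as independent findings, never merged
#' with co-occurring variants. Pseudogene-origin hybrids (5'-most site P)
#' produce no variant call.
#'
#' @param scenario a `scenario_call`.
#' @param haplotypes_cn CN-annotated haplotypes.
#' @param breakpoints data.frame from [detect_cn_transitions()].
#' @param cn_call a `copy_number_call`.
#' @param model a [paralog_model()].
#' @return data.frame of report entries: `label`, `genotype`, `mechanism`,
#'   `pathogenic`, `detail`.
#' @export
classify_recombinant <- function(scenario, haplotypes_cn, breakpoints,
                                 cn_call, model) {
  ph <- phasing_sites(model)
  entries <- list()
  add <- function(label, genotype, mechanism, pathogenic = NA,
                  detail = "") {
    entries[[length(entries) + 1L]] <<-
      data.frame(label = label, genotype = genotype, mechanism = mechanism,
                 pathogenic = pathogenic, detail = detail,
                 stringsAsFactors = FALSE)
  }

  ## CNV findings
  if (cn_call$cnv_class == "CNL") {
    cnl_bps <- breakpoints[breakpoints$kind == "CNL", , drop = FALSE]
    if (nrow(cnl_bps)) {
      for (i in seq_len(nrow(cnl_bps))) {
        pc <- classify_cnl_pathogenicity(cnl_bps[i, ], model)
        add("CNL", if (cn_call$cn_unique == 0L) "HOM" else "HET", "CNL",
            pc$pathogenic,
            if (pc$boundary) "boundary-straddling interval" else "")
      }
    } else {
      add("CNL", "HET", "CNL", NA, "no breakpoint localized")
    }
  } else if (cn_call$cnv_class == "CNG") {
    add("CNG", "HET", "CNG",
        FALSE, paste0("extra_copies=", cn_call$cn_unique - 2L))
  }

  ## variant haplotypes
  S <- nrow(ph)
  haps <- haplotypes_cn
  gene_side <- hap_is_gene_origin(haps$allele_string, haps$imputed)
  for (h in which(gene_side)) {
    al <- strsplit(haps$allele_string[h], "")[[1]]
    psites <- ph$site_id[al == "P"]
    if (!length(psites)) next
    lab <- match_recombinant(model, psites)
    unmatched <- startsWith(lab, "sites:")
    if (unmatched && !is_3prime_suffix(psites, ph$site_id)) {
      add(lab, "HET", "UNCLASSIFIED", NA,
          "pseudogene sites match no named recombinant or 3' suffix")
      next
    }
    genotype <- if (scenario$genotype %in% c("HOM", "COMPOUND_HET"))
      scenario$genotype else if (haps$cn[h] >= 2L) "HOM" else "HET"
    mech <- if (cn_call$cnv_class == "CNL" &&
                any(breakpoints$kind == "CNL" &
                    breakpoints$right_pos <= min(ph$gene_pos[al == "P"]))) {
      "CNL"
    } else if (length(psites) >= 2L) "CONVERSION" else "SNV"
    pathog <- NA
    if (mech == "CNL") pathog <- TRUE  # fusion carrying coding pseudo sites
    add(lab, genotype, mech, pathog)
  }
  if (!length(entries))
    return(data.frame(label = character(), genotype = character(),
                      mechanism = character(), pathogenic = logical(),
                      detail = character()))
  do.call(rbind, entries)
}
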