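## Internal coordinate convention: 0-based half-open intervals and 0-based
## positions. Model files on disk use 1-based inclusive positions (VCF
## convention) and are converted on load/save.

#' Construct a genomic interval
#'
#' @param contig contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @return A `genomic_interval` list with fields `contig`, `start`, `end`.
#' @export
genomic_interval <- function(contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (!nzchar(contig)) stop("genomic_interval: contig must be non-empty")
  if (is.na(start) || is.na(end) || start >= end)
    stop("genomic_interval: start must be < end (0-based half-open), got [",
         start, ", ", end, ")")
  structure(list(contig = contig, start = start, end = end),
            class = "genomic_interval")
}

interval_width <- function(x) x$end - x$start

interval_overlaps <- function(a, b) {
  a$contig == b$contig && a$start < b$end && b$start < a$end
}

interval_contains_pos <- function(x, pos) pos >= x$start && pos < x$end

#' Construct a paralog locus model
#'
#' Bundles everything the callers need to know about a gene/pseudogene pair:
#' the paralog intervals, the unique copy-number-calling region between them,
#' the high-homology phasing region, the differentiating sites, known target
#' variants and named recombinant alleles.
#'
#' @param contig contig name shared by all intervals.
#' @param gene,pseudogene,unique_cn_region,homology_region,coding_region
#'   `genomic_interval` objects (see [genomic_interval()]). `homology_region`
#'   is the exon 9-11-style phasing window and must contain exactly the
#'   phasing-set sites.
#' @param sites data.frame with columns `site_id`, `gene_pos`, `pseudo_pos`,
#'   `gene_base`, `pseudo_base`, `in_phasing_set`, `is_sentinel`, `reliable`,
#'   `is_indel`, `indel_len`. Positions are 0-based. `site_id` must be
#'   strictly increasing with `gene_pos` (5'->3' along the gene).
#' @param variants data.frame of target variants: `label`, `gene_pos`,
#'   `ref_allele`, `alt_allele`, `gbap1_like`, `in_homology_region`,
#'   `severity` (one of severe/mild/risk/unknown).
#' @param recombinants named list mapping a recombinant label (e.g.
#'   `"RecNciI"`) to the integer `site_id`s at which it carries the
#'   pseudogene base.
#' @param baseline_regions list of `genomic_interval`s used for depth
#'   normalization (regions free of paralog ambiguity).
#' @param homopolymers list of `genomic_interval`s of homopolymer runs used
#'   by the amplicon depth-anomaly detector.
#' @param diploid_cn_baseline expected combined gene+pseudogene copy number
#'   in a diploid without CNVs (default 4).
#' @return A validated object of class `paralog_model`.
#' @export
paralog_model <- function(contig, gene, pseudogene, unique_cn_region,
                          homology_region, coding_region, sites,
                          variants = empty_variants(),
                          recombinants = list(),
                          baseline_regions = list(),
                          homopolymers = list(),
                          diploid_cn_baseline = 4L) {
  m <- structure(
    list(contig = contig, gene = gene, pseudogene = pseudogene,
         unique_cn_region = unique_cn_region,
         homology_region = homology_region, coding_region = coding_region,
         sites = sites, variants = variants, recombinants = recombinants,
         baseline_regions = baseline_regions, homopolymers = homopolymers,
         diploid_cn_baseline = as.integer(diploid_cn_baseline)),
    class = "paralog_model")
  validate_model(m)
  m
}

empty_variants <- function() {
  data.frame(label = character(), gene_pos = integer(),
             ref_allele = character(), alt_allele = character(),
             gbap1_like = logical(), in_homology_region = logical(),
             severity = character(), stringsAsFactors = FALSE)
}

#' Validate a paralog model
#'
#' Checks every structural invariant of the model: interval sanity, site
#' ordering, allele distinctness, the placement of the unique CN region
#' strictly between the paralogs, and that the phasing set coincides with
#' the sites inside the homology region.
#'
#' @param m a `paralog_model`.
#' @return `m`, invisibly; stops with a field-naming error on violation.
#' @export
validate_model <- function(m) {
  fail <- function(field, msg) stop("invalid paralog_model [", field, "]: ",
                                    msg, call. = FALSE)
  for (f in c("gene", "pseudogene", "unique_cn_region", "homology_region",
              "coding_region")) {
    iv <- m[[f]]
    if (!inherits(iv, "genomic_interval")) fail(f, "not a genomic_interval")
    if (iv$contig != m$contig) fail(f, "contig mismatch")
  }
  u <- m$unique_cn_region
  if (interval_overlaps(u, m$gene) || interval_overlaps(u, m$pseudogene))
    fail("unique_cn_region", "overlaps a paralog interval")
  lo <- min(m$gene$end, m$pseudogene$end)
  hi <- max(m$gene$start, m$pseudogene$start)
  if (!(u$start >= lo && u$end <= hi))
    fail("unique_cn_region", "does not lie between gene and pseudogene")

  s <- m$sites
  need <- c("site_id", "gene_pos", "pseudo_pos", "gene_base", "pseudo_base",
            "in_phasing_set", "is_sentinel", "reliable", "is_indel",
            "indel_len")
  miss <- setdiff(need, names(s))
  if (length(miss)) fail("sites", paste("missing columns:",
                                        paste(miss, collapse = ", ")))
  if (nrow(s)) {
    if (is.unsorted(s$gene_pos, strictly = TRUE))
      fail("sites", "gene_pos not strictly increasing")
    if (any(diff(s$site_id) <= 0))
      fail("sites", "site_id not strictly increasing with gene_pos")
    if (any(s$gene_base == s$pseudo_base))
      fail("sites", "gene_base equals pseudo_base at some site")
    if (any(!vapply(s$gene_pos, interval_contains_pos, TRUE,
                    x = m$gene)))
      fail("sites", "gene_pos outside gene interval")
    in_hom <- s$gene_pos >= m$homology_region$start &
      s$gene_pos < m$homology_region$end
    if (!identical(in_hom, s$in_phasing_set))
      fail("sites",
           "phasing set must be exactly the sites inside homology_region")
  }
  if (any(s$in_phasing_set) &&
      !(m$homology_region$start >= m$gene$start &&
        m$homology_region$end <= m$gene$end))
    fail("homology_region", "not contained in the gene interval")

  v <- m$variants
  if (nrow(v)) {
    gl <- which(v$gbap1_like)
    for (i in gl) {
      j <- match(v$gene_pos[i], s$gene_pos)
      if (is.na(j) || s$pseudo_base[j] != v$alt_allele[i])
        fail("variants", paste0(v$label[i],
             ": gbap1_like but alt_allele is not the pseudo_base of a ",
             "differentiating site at that position"))
    }
    bad <- !v$severity %in% c("severe", "mild", "risk", "unknown")
    if (any(bad)) fail("variants", "severity not in severe/mild/risk/unknown")
  }

  if (length(m$recombinants)) {
    ids <- s$site_id[s$in_phasing_set]
    for (lab in names(m$recombinants)) {
      if (!all(m$recombinants[[lab]] %in% ids))
        fail("recombinants", paste0(lab, ": site_id not in phasing set"))
    }
    r <- m$recombinants
    if (all(c("RecNciI", "RecTL") %in% names(r)) &&
        !all(r$RecNciI %in% r$RecTL))
      fail("recombinants", "RecTL must be a superset of RecNciI")
    if (all(c("RecTL", "c.1263del+RecTL") %in% names(r)) &&
        !all(r$RecTL %in% r[["c.1263del+RecTL"]]))
      fail("recombinants", "c.1263del+RecTL must be a superset of RecTL")
  }
  invisible(m)
}

phasing_sites <- function(m) m$sites[m$sites$in_phasing_set, , drop = FALSE]

## ---- serialization ----------------------------------------------------

model_to_list <- function(m) {
  iv1 <- function(iv) list(contig = iv$contig, start = iv$start + 1L,
                           end = iv$end)  # 1-based inclusive on disk
  s <- m$sites
  s$gene_pos <- s$gene_pos + 1L
  s$pseudo_pos <- s$pseudo_pos + 1L
  v <- m$variants
  if (nrow(v)) v$gene_pos <- v$gene_pos + 1L
  list(format = "paralogcnv-region-model",
       version = 1L,
       contig = m$contig,
       intervals = list(gene = iv1(m$gene), pseudogene = iv1(m$pseudogene),
                        unique_cn_region = iv1(m$unique_cn_region),
                        homology_region = iv1(m$homology_region),
                        coding_region = iv1(m$coding_region)),
       baseline_regions = lapply(m$baseline_regions, iv1),
       homopolymers = lapply(m$homopolymers, iv1),
       diploid_cn_baseline = m$diploid_cn_baseline,
       sites = s, variants = v, recombinants = m$recombinants)
}

list_to_model <- function(x, path = "<list>") {
  need <- c("contig", "intervals", "sites")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed region-model file '", path, "': missing keys ",
         paste(miss, collapse = ", "))
  iv0 <- function(l) genomic_interval(l$contig, as.integer(l$start) - 1L,
                                      as.integer(l$end))
  ivlist0 <- function(x) {
    if (is.null(x)) return(list())
    if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
    lapply(unname(x), iv0)
  }
  s <- as.data.frame(x$sites, stringsAsFactors = FALSE)
  s$gene_pos <- as.integer(s$gene_pos) - 1L
  s$pseudo_pos <- as.integer(s$pseudo_pos) - 1L
  v <- if (!is.null(x$variants) && length(x$variants)) {
    vv <- as.data.frame(x$variants, stringsAsFactors = FALSE)
    if (nrow(vv)) vv$gene_pos <- as.integer(vv$gene_pos) - 1L
    vv
  } else empty_variants()
  rec <- lapply(x$recombinants, as.integer)
  paralog_model(contig = x$contig,
                gene = iv0(x$intervals$gene),
                pseudogene = iv0(x$intervals$pseudogene),
                unique_cn_region = iv0(x$intervals$unique_cn_region),
                homology_region = iv0(x$intervals$homology_region),
                coding_region = iv0(x$intervals$coding_region),
                sites = s, variants = v, recombinants = rec,
                baseline_regions = ivlist0(x$baseline_regions),
                homopolymers = ivlist0(x$homopolymers),
                diploid_cn_baseline = x$diploid_cn_baseline %||% 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a region-model file
#'
#' Reads a JSON region-model document (positions 1-based inclusive on disk)
#' and returns a validated [paralog_model()]. All invariants are checked on
#' load; a violated invariant raises an error naming the offending field.
#'
#' @param path path to a model JSON file.
#' @return A `paralog_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                error = function(e)
                  stop("malformed region-model file '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  list_to_model(x, path)
}

#' Save a region-model file
#'
#' Inverse of [load_model()]; `save_model(load_model(f), g)` writes a file
#' byte-identical to a canonically written `f`.
#'
#' @param m a `paralog_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  validate_model(m)
  json <- jsonlite::toJSON(model_to_list(m), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Export model intervals as BED
#'
#' Writes the named model intervals (and homopolymers) as a BED4 file for
#' genome-browser inspection. BED is natively 0-based half-open, matching
#' the in-memory convention.
#'
#' @param m a `paralog_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_model_bed <- function(m, path) {
  rows <- list(gene = m$gene, pseudogene = m$pseudogene,
               unique_cn_region = m$unique_cn_region,
               homology_region = m$homology_region,
               coding_region = m$coding_region)
  hp <- m$homopolymers
  if (length(hp)) names(hp) <- paste0("homopolymer_", seq_along(hp))
  rows <- c(rows, hp)
  df <- data.frame(contig = vapply(rows, `[[`, "", "contig"),
                   start = vapply(rows, `[[`, 0L, "start"),
                   end = vapply(rows, `[[`, 0L, "end"),
                   name = names(rows))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map a gene position to its homologous pseudogene position
#'
#' Piecewise-linear mapping anchored at the differentiating sites. Between
#' two adjacent anchors with equal spacing the mapping is linear; across an
#' indel-type site (a gene-only insertion) positions inside the inserted
#' span have no pseudogene homolog and raise a no-mapping error.
#'
#' @param m a `paralog_model`.
#' @param pos 0-based gene position (scalar).
#' @return 0-based pseudogene position.
#' @export
map_gene_to_pseudo <- function(m, pos) {
  s <- m$sites
  if (!nrow(s)) stop("no-mapping: model has no anchor sites")
  if (!interval_contains_pos(m$gene, pos))
    stop("no-mapping: position ", pos, " outside gene interval")
  g <- s$gene_pos; p <- s$pseudo_pos
  i <- findInterval(pos, g)
  if (i == 0L) return(p[1L] - (g[1L] - pos))       # before first anchor
  if (s$is_indel[i]) {
    ins <- s$indel_len[i]
    if (pos > g[i] && pos < g[i] + ins)
      stop("no-mapping: position ", pos,
           " lies inside a gene-only insertion (site ", s$site_id[i], ")")
    if (pos >= g[i] + ins) return(p[i] + (pos - g[i] - ins))
  }
  if (i == nrow(s)) return(p[i] + (pos - g[i]))    # beyond last anchor
  dg <- g[i + 1L] - g[i]; dp <- p[i + 1L] - p[i]
  if (pos == g[i]) return(p[i])
  if (dg == dp) return(p[i] + (pos - g[i]))
  ## unequal spacing without a declared indel site: gap location unknown
  stop("no-mapping: position ", pos, " lies between anchors with an ",
       "unanchored indel (sites ", s$site_id[i], "-", s$site_id[i + 1L], ")")
}
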