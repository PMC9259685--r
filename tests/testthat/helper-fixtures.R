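## Shared fixtures, built lazily and cached for the whole run. Everything
## is generated in code from fixed seeds; nothing binary ships with the
## package.

.fx <- new.env(parent = emptyenv())

fx_ref <- function() {
  if (is.null(.fx$ref)) .fx$ref <- build_mini_reference(1)
  .fx$ref
}

fx_dir <- function() {
  if (is.null(.fx$dir)) {
    .fx$dir <- file.path(tempdir(), "paralogcnv-fixtures")
    dir.create(.fx$dir, showWarnings = FALSE)
  }
  .fx$dir
}

## simulate (and cache) a named sample
fx_sample <- function(name, h1 = list(), h2 = list(), seed = 42,
                      depth = 30, gc_bias = 0, error_rate = 0.002) {
  key <- paste0("sim_", name)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_sample(
      fx_ref(), h1, h2,
      sim_config(depth = depth, gc_bias = gc_bias,
                 error_rate = error_rate, seed = seed),
      dir = fx_dir(), sample_id = name)
  }
  .fx[[key]]
}

fx_reads <- function(name, ...) {
  key <- paste0("reads_", name)
  if (is.null(.fx[[key]])) .fx[[key]] <- load_reads(fx_sample(name, ...)$bam)
  .fx[[key]]
}

phasing_ids <- function(model = fx_ref()$model) {
  model$sites$site_id[model$sites$in_phasing_set]
}

## a synthetic reads data.frame (no BAM) for unit tests of counting logic
make_reads <- function(qname, pos, seq, mapq = 60L, cigar = NULL,
                       qual = NULL) {
  n <- length(qname)
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep("F", nchar(seq))
  df <- data.frame(qname = qname, flag = 0L, pos = as.integer(pos),
                   mapq = as.integer(mapq), cigar = cigar, seq = seq,
                   qual = qual, stringsAsFactors = FALSE)
  df$rwidth <- paralogcnv:::cigar_ref_width(df$cigar)
  df$end <- df$pos + df$rwidth - 1L
  df[order(df$pos), , drop = FALSE]
}

## fully-informative phasing fragments: one row per fragment, typed at all
## ten sites according to a haplotype string
make_fragments <- function(hap_strings, counts, model = fx_ref()$model) {
  ph <- model$sites[model$sites$in_phasing_set, ]
  rows <- do.call(rbind, lapply(seq_along(hap_strings), function(i) {
    m <- matrix(strsplit(hap_strings[i], "")[[1]], counts[i],
                nrow(ph), byrow = TRUE)
    rownames(m) <- sprintf("f%d_%d", i, seq_len(counts[i]))
    m
  }))
  colnames(rows) <- ph$site_id
  structure(rows, class = "haplotype_fragments")
}
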