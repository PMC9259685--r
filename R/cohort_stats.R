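## Cohort-level carrier statistics: carrier exclusion, odds ratios,
## prevalences and proportion tests over per-sample carrier tables.

#' Expand printed cohort carrier counts into a per-sample table
#'
#' Turns a summary table (one row per cohort arm with carrier counts) into
#' a per-sample carrier table suitable for [exclude_carriers()] and
#' [odds_ratio()]. Within each arm, `n409s` samples are flagged as p.N409S
#' carriers; among the remaining samples `total_excl` are flagged as
#' carrying any qualifying variant, of which the first `severe` are
#' flagged severe (severe carriers are assumed not to overlap the p.N409S
#' carriers, consistent with how the counts are used after exclusion).
#'
#' @param counts data.frame with columns `cohort`, `arm` ("case" or
#'   "control"), `N`, `n409s`, `severe`, `total_excl`.
#' @return data.frame with one row per sample: `sample_id`, `cohort`,
#'   `arm`, logical flags `n409s`, `severe`, `any_variant`.
#' @export
expand_cohort_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    stopifnot(r$n409s + r$total_excl <= r$N, r$severe <= r$total_excl)
    n409s <- c(rep(TRUE, r$n409s), rep(FALSE, r$N - r$n409s))
    rest <- r$N - r$n409s
    anyv <- c(rep(FALSE, r$n409s),
              rep(TRUE, r$total_excl), rep(FALSE, rest - r$total_excl))
    sev <- c(rep(FALSE, r$n409s),
             rep(TRUE, r$severe), rep(FALSE, rest - r$severe))
    data.frame(sample_id = sprintf("%s_%s_%05d", r$cohort, r$arm,
                                   seq_len(r$N)),
               cohort = r$cohort, arm = r$arm,
               n409s = n409s, severe = sev, any_variant = anyv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exclude carriers of a variant class from both arms
#'
#' @param table per-sample cohort table with logical carrier flags.
#' @param variant_class name of the flag column to exclude on.
#' @return The table without carriers of the class; attribute `n_removed`
#'   records how many rows each arm lost.
#' @export
exclude_carriers <- function(table, variant_class) {
  if (!variant_class %in% names(table))
    stop("unknown variant class: ", variant_class)
  drop <- table[[variant_class]]
  out <- table[!drop, , drop = FALSE]
  attr(out, "n_removed") <- table(table$arm[drop])
  if (!nrow(out)) warning("all samples were carriers; table is empty")
  out
}

#' Odds ratio for an exposure between cases and controls
#'
#' Cross-product odds ratio with a 95% Wald confidence interval; for a
#' single binary covariate this equals the logistic-regression maximum
#' likelihood estimate. Zero cells receive the Haldane-Anscombe 0.5
#' correction (flagged).
#'
#' @param table per-sample cohort table with an `arm` column.
#' @param exposure_flag name of the logical exposure column.
#' @return An `odds_ratio_result`: `or_value`, `ci_low`, `ci_high`,
#'   `counts` (a, b, c, d), `corrected`.
#' @export
odds_ratio <- function(table, exposure_flag) {
  e <- table[[exposure_flag]]
  a <- sum(table$arm == "case" & e)
  b <- sum(table$arm == "case" & !e)
  c_ <- sum(table$arm == "control" & e)
  d <- sum(table$arm == "control" & !e)
  odds_ratio_counts(a, b, c_, d)
}

#' @rdname odds_ratio
#' @param a,b,c_,d the 2x2 cells: exposed/unexposed cases, then
#'   exposed/unexposed controls.
#' @export
odds_ratio_counts <- function(a, b, c_, d) {
  if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
    stop("undefined odds ratio: a margin of the 2x2 table is zero")
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  structure(list(or_value = or,
                 ci_low = exp(log(or) - 1.96 * se),
                 ci_high = exp(log(or) + 1.96 * se),
                 counts = c(a = a, b = b, c = c_, d = d),
                 corrected = corrected),
            class = "odds_ratio_result")
}

#' Carrier prevalence in one arm
#'
#' @param table per-sample cohort table.
#' @param flag carrier flag column.
#' @param arm optional arm restriction ("case"/"control").
#' @return Percentage, rounded to 1 decimal place (2 below 1%).
#' @export
prevalence <- function(table, flag, arm = NULL) {
  if (!is.null(arm)) table <- table[table$arm == arm, , drop = FALSE]
  if (!nrow(table)) stop("empty stratum")
  pct <- 100 * mean(table[[flag]])
  round(pct, if (pct < 1) 2L else 1L)
}

#' @rdname prevalence
#' @param k,n carrier and stratum counts.
#' @export
prevalence_counts <- function(k, n) {
  if (n == 0) stop("empty stratum")
  pct <- 100 * k / n
  round(pct, if (pct < 1) 2L else 1L)
}

#' Two-sample proportion test
#'
#' Compares `a/n1` against `b/n2`. Fisher's exact test by default;
#' chi-squared optional.
#'
#' @param a,n1,b,n2 carrier counts and stratum sizes.
#' @param method "fisher" (default) or "chisq".
#' @return Two-sided p-value.
#' @export
proportion_test <- function(a, n1, b, n2, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  m <- matrix(c(a, n1 - a, b, n2 - b), 2L, byrow = TRUE)
  if (method == "fisher") stats::fisher.test(m)$p.value
  else stats::chisq.test(m)$p.value
}
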