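## Concordant vs discordant tallies, bootstrap percentile intervals and
## one-sided bootstrap FDR, and stratified Fisher's exact tests.

#' Tally concordant vs discordant barcode pairs
#'
#' Counts qualifying reads per group: a read enters the tally only if it
#' passed layout validation, demultiplexed unambiguously, carries
#' separately valid BC1 and BC2, and is full length BC-to-BC (the filter
#' cascade that defines the swap denominator).
#'
#' @param parsed ParsedRead table from [parseReads()] (needs
#'   `concordant` defined, i.e. a dictionary was supplied).
#' @param by character vector of grouping columns (default
#'   `"library_id"`); any ParsedRead column (e.g. `is_dimer`,
#'   `full_itr_to_itr`) can be used as a stratifier.
#' @param require_full_length require `full_bc_to_bc` (default TRUE;
#'   set FALSE only when no window is available).
#' @return data.table with the grouping columns, `n_concordant`,
#'   `n_discordant`, `fraction_discordant` (`NA` with a warning when a
#'   group is empty).
#' @export
tallySwaps <- function(parsed, by = "library_id",
                       require_full_length = TRUE) {
  dt <- as.data.table(parsed)
  q <- dt$pass_layout & !is.na(dt$library_id) &
    dt$library_id != "ambiguous" &
    !is.na(dt$bc1_valid) & dt$bc1_valid &
    !is.na(dt$bc2_valid) & dt$bc2_valid & !is.na(dt$concordant)
  if (require_full_length)
    q <- q & !is.na(dt$full_bc_to_bc) & dt$full_bc_to_bc
  dt <- dt[q]
  if (!nrow(dt)) {
    warning("no qualifying reads")
    out <- dt[, c(by, "concordant"), with = FALSE]
    out <- out[, .(n_concordant = 0L, n_discordant = 0L,
                   fraction_discordant = NA_real_), by = by]
    return(out[])
  }
  out <- dt[, .(n_concordant = sum(concordant),
                n_discordant = sum(!concordant)), by = by]
  out[, fraction_discordant :=
        n_discordant / (n_concordant + n_discordant)]
  setorder(out)
  out[]
}

#' Bootstrap percentile interval of the discordant fraction
#'
#' Resamples reads (as Bernoulli outcomes) with replacement and reports
#' nearest-rank percentiles of the resampled discordant fraction
#' (defaults: 20th to 80th).
#'
#' @param n_concordant,n_discordant observed counts (or pass a one-row
#'   tally from [tallySwaps()] as `n_concordant`).
#' @param n_resamples bootstrap resamples (default 1e5).
#' @param lo,hi percentile bounds.
#' @param seed RNG seed.
#' @return numeric `c(low, high)` with attributes `seed`,
#'   `n_resamples`.
#' @export
bootstrapInterval <- function(n_concordant, n_discordant = NULL,
                              n_resamples = 1e5, lo = 0.20, hi = 0.80,
                              seed = 1L) {
  if (is.null(n_discordant)) {
    tally <- n_concordant
    n_concordant <- tally$n_concordant
    n_discordant <- tally$n_discordant
  }
  n <- n_concordant + n_discordant
  stopifnot(n >= 1)
  phat <- n_discordant / n
  withSeed(seed, {
    fr <- rbinom(n_resamples, n, phat) / n
    out <- nearestRankQuantile(fr, c(lo, hi))
  })
  out <- c(low = out[1], high = out[2])
  attr(out, "seed") <- seed
  attr(out, "n_resamples") <- n_resamples
  out
}

#' One-sided bootstrap false discovery rate between two samples
#'
#' Resamples both samples independently (reads as Bernoulli outcomes,
#' with replacement) and reports the fraction of resamples violating the
#' hypothesized ordering that sample `a` has the lower concordant-pair
#' fraction (i.e. more swapping) than sample `b`. Ties in the resampled
#' fractions count as half a violation, which centers `fdr(a, a)` at
#' 0.5; the strict and weak variants are reported alongside.
#'
#' @param tally_a,tally_b one-row tallies (lists or data.frames with
#'   `n_concordant`, `n_discordant`); `a` is hypothesized to swap more.
#' @param n_resamples bootstrap resamples (default 1e5).
#' @param seed RNG seed.
#' @param lo,hi percentile bounds for the per-sample intervals.
#' @return list with `fdr` (ties at half weight), `fdr_strict`,
#'   `fdr_weak`, `interval_a`, `interval_b`, `n_resamples`, `seed`.
#' @export
bootstrapFdr <- function(tally_a, tally_b, n_resamples = 1e5, seed = 1L,
                         lo = 0.20, hi = 0.80) {
  na <- tally_a$n_concordant + tally_a$n_discordant
  nb <- tally_b$n_concordant + tally_b$n_discordant
  stopifnot(na >= 1, nb >= 1)
  pa <- tally_a$n_concordant / na
  pb <- tally_b$n_concordant / nb
  withSeed(seed, {
    ca <- rbinom(n_resamples, na, pa) / na   # concordant fractions
    cb <- rbinom(n_resamples, nb, pb) / nb
    viol_strict <- ca >= cb                  # ties count as violations
    viol_weak <- ca > cb
    fdr <- mean(ca > cb) + 0.5 * mean(ca == cb)
    ia <- nearestRankQuantile(1 - ca, c(lo, hi))  # discordant-scale interval
    ib <- nearestRankQuantile(1 - cb, c(lo, hi))
    list(fdr = fdr, fdr_strict = mean(viol_strict),
         fdr_weak = mean(viol_weak),
         interval_a = c(low = ia[1], high = ia[2]),
         interval_b = c(low = ib[1], high = ib[2]),
         n_resamples = n_resamples, seed = seed)
  })
}

#' Run a plan of pairwise bootstrap-FDR comparisons
#'
#' Applies [bootstrapFdr()] to each row of a comparison plan: pairs of
#' sample ids from a tally table, with sample `a` hypothesized to swap
#' more (lower concordant fraction) than sample `b`.
#'
#' @param tallies tally table from [tallySwaps()] with a sample id
#'   column.
#' @param plan data.frame with columns `sample_a`, `sample_b`.
#' @param id_col name of the sample id column (default `"library_id"`).
#' @param n_resamples,seed passed to [bootstrapFdr()] (the seed is
#'   advanced per comparison).
#' @return data.table: one row per comparison with `fdr`, `fdr_strict`,
#'   `fdr_weak`, the two 20-80 percentile intervals, `n_resamples` and
#'   the per-comparison seed.
#' @export
compareSamples <- function(tallies, plan, id_col = "library_id",
                           n_resamples = 1e5, seed = 1L) {
  tl <- as.data.table(tallies)
  stopifnot(id_col %in% names(tl),
            all(c("sample_a", "sample_b") %in% names(plan)))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    ta <- tl[tl[[id_col]] == plan$sample_a[i]]
    tb <- tl[tl[[id_col]] == plan$sample_b[i]]
    if (nrow(ta) != 1L || nrow(tb) != 1L)
      stop("plan row ", i, ": sample ids must match exactly one tally row")
    s <- seed + i - 1L
    r <- bootstrapFdr(ta, tb, n_resamples = n_resamples, seed = s)
    data.table(sample_a = plan$sample_a[i], sample_b = plan$sample_b[i],
               fdr = r$fdr, fdr_strict = r$fdr_strict,
               fdr_weak = r$fdr_weak,
               interval_a_low = r$interval_a[["low"]],
               interval_a_high = r$interval_a[["high"]],
               interval_b_low = r$interval_b[["low"]],
               interval_b_high = r$interval_b[["high"]],
               n_resamples = n_resamples, seed = s)
  })
  rbindlist(rows)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value follows the
#' sum-of-tables-with-probability-at-most-observed convention. A table
#' with a zero margin returns p = 1 and is flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `p_value`, `odds_ratio`, `zero_margin`.
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2))$p_value
#' @export
fisherExact2x2 <- function(table, alternative = "two.sided") {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  zero_margin <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (zero_margin)
    return(list(p_value = 1, odds_ratio = NA_real_, zero_margin = TRUE))
  ft <- stats::fisher.test(table, alternative = alternative)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       zero_margin = FALSE)
}
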