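#' Wilcoxon matched-pairs signed-rank test
#'
#' Classic signed-rank test on paired differences.  Zero differences are
#' dropped; the absolute values of the remainder are ranked (midranks for
#' ties) and `W` is the smaller of the positive- and negative-rank sums.
#' When there are no ties among the absolute differences and the effective
#' sample size is at most `exact_limit`, the two-sided p-value is exact:
#' the probability, over all sign assignments to the ranks, that the
#' smaller rank sum is at most the observed `W` (computed by subset-sum
#' counting, which enumerates the full sign-assignment distribution).
#' Otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param diffs Numeric vector of paired differences (NAs dropped).
#' @param exact_limit Largest effective n for which the exact distribution
#'   is used (default 25).
#' @return A list with `W`, `p_value` (two-sided), `n_used` (after zero
#'   removal), `n_zero`, `method` (`"exact"`, `"normal"` or
#'   `"degenerate"`) and `degenerate` (`TRUE` when every difference is
#'   zero, in which case `p_value` is 1).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value  # 2 / 2^5 = 0.0625
#' @export
wilcoxon_signed_rank <- function(diffs, exact_limit = 25) {
  d <- diffs[!is.na(diffs)]
  if (length(d) < 1) {
    stop("at least one difference is required", call. = FALSE)
  }
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  n <- length(nz)
  if (n == 0) {
    return(list(W = 0, p_value = 1, n_used = 0L, n_zero = n_zero,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(nz))
  splus <- sum(r[nz > 0])
  sminus <- sum(r[nz < 0])
  W <- min(splus, sminus)
  has_ties <- anyDuplicated(abs(nz)) > 0
  if (!has_ties && n <= exact_limit) {
    counts <- signrank_counts(n)
    total <- n * (n + 1) / 2
    sums <- 0:total
    p <- sum(counts[sums <= W | sums >= total - W]) / 2^n
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      return(list(W = W, p_value = 1, n_used = as.integer(n),
                  n_zero = n_zero, method = "degenerate",
                  degenerate = TRUE))
    }
    z <- splus - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = W, p_value = min(1, p), n_used = as.integer(n),
       n_zero = n_zero, method = method, degenerate = FALSE)
}

# Number of subsets of ranks 1..n attaining each sum 0..n(n+1)/2, i.e. the
# unnormalized exact null distribution of the positive-rank sum.  Counts
# stay below 2^25 << 2^53, so doubles are exact.
signrank_counts <- function(n) {
  f <- 1
  for (r in seq_len(n)) {
    f <- c(f, numeric(r)) + c(numeric(r), f)
  }
  f
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons `m` and caps at 1.
#' `m` may exceed the number of p-values supplied (e.g. when a run reports
#' a subset of the comparisons actually performed) but may not be smaller.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of comparisons (default `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop(sprintf("m (%d) is smaller than the number of p-values (%d)",
                 m, length(p_values)), call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Summary statistics for one locus-versus-locus matched table
#'
#' Computes, over the matched species pairs, the signed-rank test of
#' `d_y - d_x` and the fractions used to read variability scatterplots:
#' the fraction of pairs below the 1:1 line (`d_y < d_x`; ties count in
#' the denominator but never the numerator) and the fractions strictly
#' above the 2:1 and 4:1 lines (`d_y > 2 d_x`, `d_y > 4 d_x`; pairs with
#' `d_x = 0` and `d_y > 0` exceed every ratio line, pairs exactly on a
#' line do not count as exceeding it).
#'
#' @param matched A [matched_pairs()] table.
#' @param m Number of comparisons for the Bonferroni adjustment of the
#'   signed-rank p-value; `NA` (default) leaves `p_adjusted` as `NA`, to
#'   be filled by the caller that knows how many locus pairs were tested.
#' @return A one-row data frame with columns `locus_x`, `locus_y`,
#'   `n_pairs`, `n_zero_diffs`, `W`, `p_value`, `p_adjusted`,
#'   `frac_y_lt_x`, `frac_y_gt_x`, `frac_y_gt_2x`, `frac_y_gt_4x`.
#' @export
ratio_summary <- function(matched, m = NA) {
  if (nrow(matched) == 0) {
    stop("matched table is empty", call. = FALSE)
  }
  dx <- matched$d_x
  dy <- matched$d_y
  n <- length(dx)
  wt <- wilcoxon_signed_rank(dy - dx)
  data.frame(
    locus_x = attr(matched, "locus_x") %||% "x",
    locus_y = attr(matched, "locus_y") %||% "y",
    n_pairs = n,
    n_zero_diffs = sum(dy == dx),
    W = wt$W,
    p_value = wt$p_value,
    p_adjusted = if (is.na(m)) NA_real_ else bonferroni(wt$p_value, m),
    frac_y_lt_x = sum(dy < dx) / n,
    frac_y_gt_x = sum(dy > dx) / n,
    frac_y_gt_2x = sum(dy > 2 * dx) / n,
    frac_y_gt_4x = sum(dy > 4 * dx) / n,
    stringsAsFactors = FALSE
  )
}

#' Pairwise locus-variability comparison report
#'
#' Runs [ratio_summary()] for every unordered pair of loci (in the order
#' given), pooling species pairs across groups, and applies a Bonferroni
#' correction over all comparisons performed.
#'
#' @param pair_table Output of [species_pair_table()].
#' @param loci Locus columns to compare; defaults to the table's `"loci"`
#'   attribute.
#' @param m Number of comparisons for the Bonferroni correction; defaults
#'   to the number of locus pairs tested (`choose(length(loci), 2)`).
#' @return A data frame with one [ratio_summary()] row per locus pair
#'   (`locus_x` earlier in `loci` than `locus_y`).
#' @export
compare_loci <- function(pair_table, loci = attr(pair_table, "loci"),
                         m = NULL) {
  if (is.null(loci) || length(loci) < 2) {
    stop("at least two loci are required", call. = FALSE)
  }
  combos <- utils::combn(loci, 2)
  if (is.null(m)) m <- ncol(combos)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    mt <- matched_pairs(pair_table, combos[1, k], combos[2, k])
    if (nrow(mt) == 0) return(NULL)
    ratio_summary(mt, m = m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
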