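#' Compare two aligned sequences site by site
#'
#' Tallies the quantities needed for uncorrected p-distance and the Kimura
#' two-parameter (K2P) distance under pairwise deletion.  Columns where
#' either sequence has a gap (`-`) or missing data (`N`, `?`, `X`) are
#' excluded from the comparable sites.  Columns where both residues are
#' unambiguous contribute an integer mismatch classified as a transition
#' (A/G, C/T) or a transversion.  Columns involving an IUPAC ambiguity code
#' contribute the expected mismatch weight under uniform resolution over the
#' code's compatible states; the accumulated ambiguity mass is then split
#' between transitions and transversions in proportion to the unambiguous
#' changes already observed for the pair (50/50 when there are none), i.e.
#' ambiguous substitutions are distributed proportionally to unambiguous
#' changes.
#'
#' @param row_a,row_b Character vectors of equal length over the alignment
#'   alphabet (case-insensitive; `U` is read as `T`).
#' @return An object of class `"pair_comparison"`: a list with elements
#'   `comparable_sites`, `mismatch_weight`, `n_transitions`,
#'   `n_transversions`, `ambiguity_weight`, and the proportions `P`
#'   (transitions) and `Q` (transversions), which satisfy
#'   `P + Q == mismatch_weight / comparable_sites`.
#' @seealso [p_distance()], [k2p_distance()], [distance_matrix()]
#' @examples
#' cmp <- compare_pair(strsplit("ACGTACGT", "")[[1]],
#'                     strsplit("ACCTACGA", "")[[1]])
#' cmp$mismatch_weight  # 2 transversions
#' p_distance(cmp)      # 0.25
#' @export
compare_pair <- function(row_a, row_b) {
  if (length(row_a) != length(row_b)) {
    stop(sprintf("rows have unequal lengths (%d vs %d)",
                 length(row_a), length(row_b)), call. = FALSE)
  }
  a <- encode_residues(toupper(row_a), "row_a")
  b <- encode_residues(toupper(row_b), "row_b")
  compare_codes(a, b)
}

# Fast path on integer codes (see alphabet.R); used by distance_matrix().
compare_codes <- function(a, b) {
  idx <- (a - 1L) * 16L + b
  comparable <- sum(.fb_pair$comparable[idx])
  nts <- sum(.fb_pair$ts[idx])
  ntv <- sum(.fb_pair$tv[idx])
  amb <- .fb_pair$ambig[idx]
  amb_w <- if (any(amb)) sum(.fb_pair$weight[idx[amb]]) else 0
  mism <- nts + ntv + amb_w
  if (comparable > 0) {
    n_unamb <- nts + ntv
    if (n_unamb > 0) {
      wts <- amb_w * nts / n_unamb
    } else {
      wts <- amb_w / 2
    }
    P <- (nts + wts) / comparable
    Q <- (mism - nts - wts) / comparable
  } else {
    P <- Q <- NA_real_
  }
  structure(
    list(comparable_sites = comparable,
         mismatch_weight = mism,
         n_transitions = nts,
         n_transversions = ntv,
         ambiguity_weight = amb_w,
         P = P, Q = Q),
    class = "pair_comparison"
  )
}

#' Uncorrected p-distance from a pair comparison
#'
#' The proportion of differing sites among comparable sites,
#' `mismatch_weight / comparable_sites`.  Returns `NA` (an explicit
#' "undefined" marker, never a silent 0) when fewer than `min_sites`
#' columns are comparable.
#'
#' @param comparison A [compare_pair()] result.
#' @param min_sites Minimum number of comparable sites required for the
#'   distance to be defined.  Default 1.
#' @return A number in `[0, 1]`, or `NA_real_` when undefined.
#' @export
p_distance <- function(comparison, min_sites = 1) {
  if (comparison$comparable_sites < min_sites ||
      comparison$comparable_sites == 0) {
    return(NA_real_)
  }
  comparison$mismatch_weight / comparison$comparable_sites
}

#' Kimura two-parameter distance from a pair comparison
#'
#' `d = -(1/2) * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are
#' the transition and transversion proportions.  Returns `NA` when the pair
#' has fewer than `min_sites` comparable sites or when the formula's domain
#' is violated (saturation: `1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#'
#' @inheritParams p_distance
#' @return A non-negative number, or `NA_real_` when undefined.
#' @export
k2p_distance <- function(comparison, min_sites = 1) {
  if (comparison$comparable_sites < min_sites ||
      comparison$comparable_sites == 0) {
    return(NA_real_)
  }
  a1 <- 1 - 2 * comparison$P - comparison$Q
  a2 <- 1 - 2 * comparison$Q
  if (a1 <= 0 || a2 <= 0) {
    return(NA_real_)
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise distance table for one locus alignment
#'
#' Computes all `n(n-1)/2` pairwise distances under pairwise deletion.
#' Undefined entries (overlap below `min_sites`, or K2P saturation) are
#' kept as `NA`, never coerced to zero: downstream discrimination logic
#' must distinguish "identical" from "no data".
#'
#' @param alignment A [locus_alignment()].
#' @param metric `"p"` (uncorrected p-distance, the default) or `"k2p"`.
#' @param min_sites Minimum comparable sites per pair; pairs below the
#'   threshold are marked undefined.  Default 1.
#' @return An object of class `"distance_table"`: a list with the locus
#'   name, `sample_ids`, the `metric` and `min_sites` used, a symmetric
#'   numeric matrix `d` (with `NA` for undefined entries) and an integer
#'   matrix `sites` of comparable-site counts.  Use
#'   [as.data.frame.distance_table()] for the long form and
#'   [write_distance_table()] to serialize.
#' @examples
#' aln <- locus_alignment("toy", rbind(s1 = strsplit("ACGT", "")[[1]],
#'                                     s2 = strsplit("ACGA", "")[[1]]))
#' distance_matrix(aln)$d
#' @export
distance_matrix <- function(alignment, metric = c("p", "k2p"),
                            min_sites = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(alignment, "locus_alignment"))
  ids <- alignment$sample_ids
  n <- length(ids)
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  tab <- structure(
    list(locus = alignment$locus, sample_ids = ids, metric = metric,
         min_sites = min_sites, d = d, sites = sites),
    class = "distance_table"
  )
  if (n < 2) {
    warning(sprintf("alignment '%s' has %d sequence(s); empty distance table",
                    alignment$locus, n))
    return(tab)
  }
  codes <- encode_residues(alignment$matrix,
                           context = sprintf("alignment '%s'", alignment$locus))
  dist_fun <- if (metric == "p") p_distance else k2p_distance
  diag(d) <- 0
  diag(sites) <- alignment$length
  for (i in seq_len(n - 1)) {
    ci <- codes[i, ]
    for (j in seq(i + 1, n)) {
      cmp <- compare_codes(ci, codes[j, ])
      val <- dist_fun(cmp, min_sites = min_sites)
      d[i, j] <- d[j, i] <- val
      sites[i, j] <- sites[j, i] <- cmp$comparable_sites
    }
  }
  tab$d <- d
  tab$sites <- sites
  tab
}

#' @export
print.distance_table <- function(x, ...) {
  n <- length(x$sample_ids)
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("Distance table: locus '%s', %d samples, metric %s (min_sites=%d)\n",
              x$locus, n, x$metric, x$min_sites))
  if (length(off)) {
    cat(sprintf("  %d pairs, %d undefined; range of defined: [%.4g, %.4g]\n",
                length(off), sum(is.na(off)),
                suppressWarnings(min(off, na.rm = TRUE)),
                suppressWarnings(max(off, na.rm = TRUE))))
  }
  invisible(x)
}

#' Long-form view of a distance table
#'
#' @param x A `"distance_table"`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data frame with columns `sample_a`, `sample_b`, `locus`,
#'   `distance` (`NA` when undefined) and `comparable_sites`, one row per
#'   unordered sample pair, in the order of the alignment.
#' @export
as.data.frame.distance_table <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  n <- length(x$sample_ids)
  if (n < 2) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      locus = character(), distance = numeric(),
                      comparable_sites = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- which(upper.tri(x$d), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  data.frame(
    sample_a = x$sample_ids[pairs[, "row"]],
    sample_b = x$sample_ids[pairs[, "col"]],
    locus = x$locus,
    distance = x$d[pairs],
    comparable_sites = x$sites[pairs],
    stringsAsFactors = FALSE
  )
}

# Distance between two named samples; NA when undefined.
dt_entry <- function(table, a, b) {
  table$d[a, b]
}
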