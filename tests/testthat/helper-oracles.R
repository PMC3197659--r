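# Independent brute-force oracles.  These deliberately re-derive every
# quantity from first principles (per-character loops, literal
# enumeration) and share no code with the implementation under test.

.oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T")
)

# Site-by-site tallies for a pair of aligned sequences (character
# vectors, uppercase).  Gap '-' and missing 'N','?','X' columns are
# skipped; expected mismatch of ambiguous columns via double loop over
# resolutions.
oracle_pair <- function(a, b) {
  stopifnot(length(a) == length(b))
  skip <- c("-", "N", "?", "X")
  comparable <- 0L
  nts <- 0L
  ntv <- 0L
  amb <- 0
  is_ts <- function(x, y) {
    (x == "A" && y == "G") || (x == "G" && y == "A") ||
      (x == "C" && y == "T") || (x == "T" && y == "C")
  }
  for (i in seq_along(a)) {
    if (a[i] %in% skip || b[i] %in% skip) next
    comparable <- comparable + 1L
    sa <- .oracle_sets[[a[i]]]
    sb <- .oracle_sets[[b[i]]]
    if (length(sa) == 1 && length(sb) == 1) {
      if (sa != sb) {
        if (is_ts(sa, sb)) nts <- nts + 1L else ntv <- ntv + 1L
      }
    } else {
      mism <- 0L
      for (x in sa) for (y in sb) if (x != y) mism <- mism + 1L
      amb <- amb + mism / (length(sa) * length(sb))
    }
  }
  mismatch <- nts + ntv + amb
  if (comparable > 0) {
    if (nts + ntv > 0) {
      wts <- amb * nts / (nts + ntv)
    } else {
      wts <- amb / 2
    }
    P <- (nts + wts) / comparable
    Q <- (mismatch - nts - wts) / comparable
  } else {
    P <- Q <- NA_real_
  }
  list(comparable = comparable, mismatch = mismatch, nts = nts,
       ntv = ntv, amb = amb, P = P, Q = Q)
}

oracle_p <- function(a, b) {
  o <- oracle_pair(a, b)
  if (o$comparable == 0) return(NA_real_)
  o$mismatch / o$comparable
}

oracle_k2p <- function(a, b) {
  o <- oracle_pair(a, b)
  if (o$comparable == 0) return(NA_real_)
  a1 <- 1 - 2 * o$P - o$Q
  a2 <- 1 - 2 * o$Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1 * sqrt(a2))
}

# Literal 2^n enumeration of all sign assignments for the signed-rank
# test; two-sided p = fraction of assignments whose smaller rank sum is
# at most the observed one.  Zeros must already be removed.
oracle_wilcoxon_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    splus <- sum(r[signs])
    if (min(splus, total - splus) <= w_obs) count <- count + 1L
  }
  count / 2^n
}

# Independent evaluation of the species-discrimination rule from raw
# per-locus distance matrices (NA = undefined).
oracle_discrimination <- function(dmats, metadata, loci, rule,
                                  concat_dmat = NULL) {
  species <- sort(unique(metadata$species))
  sample_species <- stats::setNames(metadata$species, metadata$sample_id)
  intra_max <- function(dm, sp) {
    ids <- intersect(names(sample_species)[sample_species == sp],
                     rownames(dm))
    if (length(ids) < 2) return(0)
    vals <- dm[ids, ids][upper.tri(dm[ids, ids])]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) 0 else max(vals)
  }
  pair_ok_one <- function(dm, sa, sb) {
    ia <- intersect(names(sample_species)[sample_species == sa],
                    rownames(dm))
    ib <- intersect(names(sample_species)[sample_species == sb],
                    rownames(dm))
    if (!length(ia) || !length(ib)) return("no_data")
    dd <- dm[ia, ib, drop = FALSE]
    dd <- dd[!is.na(dd)]
    if (!length(dd)) return("no_data")
    thr <- max(intra_max(dm, sa), intra_max(dm, sb))
    if (all(dd > 0) && all(dd > thr)) "distinguished" else "not_distinguished"
  }
  disc <- logical(length(species))
  names(disc) <- species
  for (sp in species) disc[sp] <- TRUE
  for (i in seq_len(length(species) - 1)) {
    for (j in seq(i + 1, length(species))) {
      sa <- species[i]
      sb <- species[j]
      if (rule == "union") {
        vs <- vapply(loci, function(l) pair_ok_one(dmats[[l]], sa, sb),
                     character(1))
        ok <- any(vs == "distinguished")
      } else {
        ok <- pair_ok_one(concat_dmat, sa, sb) == "distinguished"
      }
      if (!ok) {
        disc[sa] <- FALSE
        disc[sb] <- FALSE
      }
    }
  }
  100 * sum(disc) / length(species)
}

# Naive concatenated p-distance matrix built with the per-character
# oracle; samples missing a locus are padded with '?'.
oracle_concat_dmat <- function(alignments, loci) {
  ids <- unique(unlist(lapply(alignments[loci], function(a) a$sample_ids)))
  rows <- lapply(ids, function(id) {
    unlist(lapply(loci, function(l) {
      aln <- alignments[[l]]
      if (id %in% aln$sample_ids) aln$matrix[id, ] else
        rep("?", aln$length)
    }))
  })
  n <- length(ids)
  dm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(dm) <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dm[i, j] <- dm[j, i] <- oracle_p(rows[[i]], rows[[j]])
    }
  }
  dm
}
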