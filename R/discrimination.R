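#' Can one locus distinguish a pair of species?
#'
#' A species pair is scored as distinguished when the interspecific
#' distance is always greater than zero and greater than the intraspecific
#' distance: every defined cross-species sample-pair distance must exceed
#' both 0 and the larger of the two species' maximum intraspecific
#' distances (enforced through the minimum cross distance; ties fail).
#' Pairs with no defined cross distance get verdict `"no_data"`.
#'
#' @param species_a,species_b Species names (must occur in `metadata`).
#' @param dist_table A `"distance_table"` for the locus.
#' @param intra Output of [intraspecific_summary()] for the same locus.
#' @param metadata Data frame with `sample_id` and `species`.
#' @return One of `"distinguished"`, `"not_distinguished"`, `"no_data"`.
#' @export
pair_distinguished <- function(species_a, species_b, dist_table, intra,
                               metadata) {
  for (sp in c(species_a, species_b)) {
    if (!sp %in% metadata$species) {
      stop(sprintf("unknown species '%s'", sp), call. = FALSE)
    }
  }
  ids <- dist_table$sample_ids
  sa <- intersect(metadata$sample_id[metadata$species == species_a], ids)
  sb <- intersect(metadata$sample_id[metadata$species == species_b], ids)
  if (length(sa) == 0 || length(sb) == 0) return("no_data")
  dd <- dist_table$d[sa, sb, drop = FALSE]
  dd <- dd[!is.na(dd)]
  if (length(dd) == 0) return("no_data")
  thr <- max(intra$max_intra[intra$species == species_a],
             intra$max_intra[intra$species == species_b], 0)
  if (min(dd) > 0 && min(dd) > thr) "distinguished" else "not_distinguished"
}

#' Species discrimination by a locus or locus combination
#'
#' Applies the pairwise rule of [pair_distinguished()] to every species
#' pair in the metadata and aggregates to species level: a species is
#' discriminated only when every pair involving it is distinguished.  Two
#' combination rules are supported.  `"union"` scores a pair as
#' distinguished when at least one constituent locus distinguishes it
#' (verdict `"no_data"` only when every locus lacks data for the pair).
#' `"concatenation"` recomputes distances on the column-wise concatenation
#' of the locus alignments (samples missing a locus are padded with
#' missing characters) and applies the single-locus rule to the result.
#'
#' @param dist_tables Named list of `"distance_table"` objects, one per
#'   locus.
#' @param metadata Data frame with `sample_id` and `species`.
#' @param loci Locus names to use (default: all of `dist_tables`).
#' @param combine_rule `"union"` (default) or `"concatenation"`.
#' @param alignments Named list of [locus_alignment()] objects; required
#'   for `combine_rule = "concatenation"`.
#' @param metric,min_sites Distance settings for the concatenated
#'   alignment (defaults taken from the first distance table).
#' @return An object of class `"discrimination_result"`: a list with
#'   `loci`, `combine_rule`, `per_pair` (data frame `species_a`,
#'   `species_b`, `verdict`), `discriminated` (character vector of
#'   species), `n_species` and `success_rate` (percentage).
#' @export
species_discrimination <- function(dist_tables, metadata,
                                   loci = names(dist_tables),
                                   combine_rule = c("union", "concatenation"),
                                   alignments = NULL,
                                   metric = NULL, min_sites = NULL) {
  combine_rule <- match.arg(combine_rule)
  if (is.null(names(dist_tables)) || any(!nzchar(names(dist_tables)))) {
    names(dist_tables) <- vapply(dist_tables, `[[`, character(1), "locus")
  }
  if (length(loci) == 0) stop("'loci' must be nonempty", call. = FALSE)
  absent <- setdiff(loci, names(dist_tables))
  if (length(absent)) {
    stop(sprintf("no distance table for locus/loci: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  species <- sort(unique(metadata$species))
  if (length(species) < 2) {
    stop("at least two species are required", call. = FALSE)
  }
  pairs <- utils::combn(species, 2)

  if (combine_rule == "union" || length(loci) == 1) {
    verdicts <- matrix(NA_character_, ncol(pairs), length(loci),
                       dimnames = list(NULL, loci))
    for (locus in loci) {
      tab <- dist_tables[[locus]]
      intra <- intraspecific_summary(tab, metadata)
      for (k in seq_len(ncol(pairs))) {
        verdicts[k, locus] <- pair_distinguished(
          pairs[1, k], pairs[2, k], tab, intra, metadata)
      }
    }
    verdict <- apply(verdicts, 1, function(v) {
      if (any(v == "distinguished")) "distinguished"
      else if (all(v == "no_data")) "no_data"
      else "not_distinguished"
    })
  } else {
    if (is.null(alignments)) {
      stop("combine_rule = \"concatenation\" requires 'alignments'",
           call. = FALSE)
    }
    first <- dist_tables[[loci[1]]]
    concat <- concatenate_loci(alignments, loci)
    tab <- distance_matrix(concat,
                           metric = metric %||% first$metric,
                           min_sites = min_sites %||% first$min_sites)
    intra <- intraspecific_summary(tab, metadata)
    verdict <- vapply(seq_len(ncol(pairs)), function(k) {
      pair_distinguished(pairs[1, k], pairs[2, k], tab, intra, metadata)
    }, character(1))
  }

  per_pair <- data.frame(species_a = pairs[1, ], species_b = pairs[2, ],
                         verdict = verdict, stringsAsFactors = FALSE)
  disc <- vapply(species, function(sp) {
    involved <- per_pair$verdict[per_pair$species_a == sp |
                                 per_pair$species_b == sp]
    all(involved == "distinguished")
  }, logical(1))
  structure(
    list(loci = loci, combine_rule = combine_rule, per_pair = per_pair,
         discriminated = species[disc], n_species = length(species),
         success_rate = 100 * sum(disc) / length(species)),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Discrimination by %s (%s rule): %d/%d species (%.1f%%)\n",
              paste(x$loci, collapse = "+"), x$combine_rule,
              length(x$discriminated), x$n_species, x$success_rate))
  invisible(x)
}

#' Concatenate locus alignments column-wise
#'
#' Builds a single alignment over the union of sample ids; samples missing
#' a locus are padded with `?` (missing) for that locus's columns, so the
#' pairwise-deletion distances simply ignore the absent locus.
#'
#' @param alignments Named list of [locus_alignment()] objects.
#' @param loci Loci to concatenate, in order (default all).
#' @return A [locus_alignment()] named by joining the loci with `+`.
#' @export
concatenate_loci <- function(alignments, loci = NULL) {
  alignments <- name_alignments(alignments)
  if (is.null(loci)) loci <- names(alignments)
  absent <- setdiff(loci, names(alignments))
  if (length(absent)) {
    stop(sprintf("no alignment for locus/loci: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  ids <- unique(unlist(lapply(alignments[loci], `[[`, "sample_ids")))
  blocks <- lapply(loci, function(locus) {
    aln <- alignments[[locus]]
    block <- matrix("?", length(ids), aln$length,
                    dimnames = list(ids, NULL))
    block[aln$sample_ids, ] <- aln$matrix
    block
  })
  locus_alignment(paste(loci, collapse = "+"), do.call(cbind, blocks))
}

#' Tabulate discrimination success rates
#'
#' @param results A list of `"discrimination_result"` objects (or a single
#'   one).
#' @return A data frame with one row per locus set: `loci` (joined with
#'   `+`), `combine_rule`, `n_species`, `n_discriminated` and
#'   `success_rate` rounded to one decimal.
#' @export
success_rate_table <- function(results) {
  if (inherits(results, "discrimination_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(loci = paste(r$loci, collapse = "+"),
               combine_rule = r$combine_rule,
               n_species = r$n_species,
               n_discriminated = length(r$discriminated),
               success_rate = round(r$success_rate, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
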