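#' Species-level interspecific divergences within groups
#'
#' Forms all species pairs within each value of the grouping column
#' (e.g. taxonomic order for broad comparisons, or a single genus for focal
#' datasets) and summarizes, per pair, the distances between their samples.
#' For species represented by several individuals the pair divergence is
#' the mean over all defined cross-species sample-pair distances; pairs
#' with no defined cross distance are kept with divergence `NA`.
#'
#' @param dist_table A `"distance_table"` for one locus.
#' @param metadata Data frame with `sample_id`, `species`, `group`.
#' @param group_by Metadata column used for grouping (default `"group"`).
#' @param group_alias Optional named character vector merging group labels,
#'   e.g. `c(Psilotales = "Psilotopsida", Ophioglossales = "Psilotopsida")`
#'   to pool classes whose orders are too small to compare alone.
#' @return A data frame with columns `group`, `species_a`, `species_b`
#'   (sorted within pair), `divergence` and `n_sample_pairs` (number of
#'   defined cross-species sample pairs), with the locus name in attribute
#'   `"locus"`.  Groups with fewer than two species contribute no rows.
#' @export
interspecific_pairs <- function(dist_table, metadata, group_by = "group",
                                group_alias = NULL) {
  stopifnot(inherits(dist_table, "distance_table"))
  md <- check_partition_metadata(dist_table, metadata, group_by, group_alias)
  out <- list()
  for (g in unique(md$grp)) {
    sub <- md[md$grp == g, ]
    species <- sort(unique(sub$species))
    if (length(species) < 2) {
      message(sprintf("group '%s' has %d species; no interspecific pairs",
                      g, length(species)))
      next
    }
    for (i in seq_len(length(species) - 1)) {
      for (j in seq(i + 1, length(species))) {
        sa <- sub$sample_id[sub$species == species[i]]
        sb <- sub$sample_id[sub$species == species[j]]
        dd <- dist_table$d[sa, sb, drop = FALSE]
        ok <- !is.na(dd)
        out[[length(out) + 1L]] <- data.frame(
          group = g, species_a = species[i], species_b = species[j],
          divergence = if (any(ok)) mean(dd[ok]) else NA_real_,
          n_sample_pairs = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(), species_a = character(),
               species_b = character(), divergence = numeric(),
               n_sample_pairs = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "locus") <- dist_table$locus
  res
}

#' Matched species-pair divergences across several loci
#'
#' Runs [interspecific_pairs()] per locus and joins on the species pair,
#' producing one divergence column per locus (named after the locus).
#' A pair absent from a locus (species without sequences there, or no
#' defined cross distances) carries `NA` in that column.
#'
#' @param dist_tables Named list of `"distance_table"` objects, one per
#'   locus (names default to each table's locus).
#' @inheritParams interspecific_pairs
#' @return A data frame with columns `group`, `species_a`, `species_b` and
#'   one numeric divergence column per locus; attribute `"loci"` lists the
#'   locus columns in input order.
#' @export
species_pair_table <- function(dist_tables, metadata, group_by = "group",
                               group_alias = NULL) {
  if (is.null(names(dist_tables)) || any(!nzchar(names(dist_tables)))) {
    names(dist_tables) <- vapply(dist_tables, `[[`, character(1), "locus")
  }
  loci <- names(dist_tables)
  merged <- NULL
  for (locus in loci) {
    pr <- interspecific_pairs(dist_tables[[locus]], metadata,
                              group_by = group_by,
                              group_alias = group_alias)
    pr <- pr[c("group", "species_a", "species_b", "divergence")]
    names(pr)[4] <- locus
    merged <- if (is.null(merged)) pr else
      merge(merged, pr, by = c("group", "species_a", "species_b"),
            all = TRUE)
  }
  merged <- merged[order(merged$group, merged$species_a, merged$species_b), ]
  rownames(merged) <- NULL
  attr(merged, "loci") <- loci
  merged
}

#' Maximum intraspecific divergence per species
#'
#' For each species with at least one sample in the table, the maximum
#' defined distance among its own samples.  Species with a single sampled
#' individual (or with no defined within-species pair) have maximum 0 by
#' convention: with no evidence of intraspecific variation, only the
#' "interspecific distance greater than zero" clause of the discrimination
#' rule binds.
#'
#' @inheritParams interspecific_pairs
#' @return A data frame with columns `species`, `max_intra`,
#'   `n_individuals`; locus name in attribute `"locus"`.
#' @export
intraspecific_summary <- function(dist_table, metadata) {
  stopifnot(inherits(dist_table, "distance_table"))
  md <- check_partition_metadata(dist_table, metadata, group_by = NULL)
  species <- sort(unique(md$species))
  res <- data.frame(species = species,
                    max_intra = 0,
                    n_individuals = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_along(species)) {
    ids <- md$sample_id[md$species == species[k]]
    res$n_individuals[k] <- length(ids)
    if (length(ids) >= 2) {
      dd <- dist_table$d[ids, ids, drop = FALSE]
      vals <- dd[upper.tri(dd)]
      vals <- vals[!is.na(vals)]
      if (length(vals)) res$max_intra[k] <- max(vals)
    }
  }
  attr(res, "locus") <- dist_table$locus
  res
}

#' Species pairs with divergence defined at both of two loci
#'
#' The matched-pairs view behind locus-versus-locus scatterplots and the
#' signed-rank comparison of locus variability.
#'
#' @param pair_table Output of [species_pair_table()].
#' @param locus_x,locus_y Locus column names; `locus_x` is the reference
#'   (x-axis) locus.
#' @return Data frame with columns `group`, `species_a`, `species_b`,
#'   `d_x`, `d_y`; attributes `"locus_x"` and `"locus_y"`.  Warns when no
#'   pair has both loci defined.
#' @export
matched_pairs <- function(pair_table, locus_x, locus_y) {
  for (l in c(locus_x, locus_y)) {
    if (!l %in% names(pair_table)) {
      stop(sprintf("locus '%s' is not a column of the pair table", l),
           call. = FALSE)
    }
  }
  keep <- !is.na(pair_table[[locus_x]]) & !is.na(pair_table[[locus_y]])
  out <- data.frame(
    group = pair_table$group[keep],
    species_a = pair_table$species_a[keep],
    species_b = pair_table$species_b[keep],
    d_x = pair_table[[locus_x]][keep],
    d_y = pair_table[[locus_y]][keep],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) {
    warning(sprintf("no species pair has both '%s' and '%s' defined",
                    locus_x, locus_y))
  }
  attr(out, "locus_x") <- locus_x
  attr(out, "locus_y") <- locus_y
  out
}

#' Mean interspecific divergence for one locus
#'
#' Arithmetic mean of the defined species-pair divergences for a locus,
#' optionally restricted to one group.
#'
#' @param pair_table Output of [species_pair_table()] (or of
#'   [interspecific_pairs()], in which case use `locus = "divergence"`).
#' @param locus Locus column name.
#' @param group Optional group label to restrict to.
#' @return The mean, or `NA_real_` when no record is defined.
#' @export
mean_divergence <- function(pair_table, locus, group = NULL) {
  if (!locus %in% names(pair_table)) {
    stop(sprintf("locus '%s' is not a column of the pair table", locus),
         call. = FALSE)
  }
  vals <- pair_table[[locus]]
  if (!is.null(group)) vals <- vals[pair_table$group %in% group]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

# Shared checks: table samples covered by metadata; species confined to a
# single group.  Returns the metadata rows for the table's samples with a
# `grp` column (aliases applied) when group_by is given.
check_partition_metadata <- function(dist_table, metadata, group_by,
                                     group_alias = NULL) {
  missing <- setdiff(dist_table$sample_ids, metadata$sample_id)
  if (length(missing)) {
    stop(sprintf("samples missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  md <- metadata[match(dist_table$sample_ids, metadata$sample_id), ]
  if (!is.null(group_by)) {
    if (!group_by %in% names(metadata)) {
      stop(sprintf("metadata has no column '%s'", group_by), call. = FALSE)
    }
    grp <- md[[group_by]]
    if (!is.null(group_alias)) {
      hit <- grp %in% names(group_alias)
      grp[hit] <- unname(group_alias[grp[hit]])
    }
    md$grp <- grp
    span <- unique(md[c("species", "grp")])
    dup <- span$species[duplicated(span$species)]
    if (length(dup)) {
      stop(sprintf("species assigned to more than one group: %s",
                   paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
  }
  md
}
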