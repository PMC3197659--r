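#' Configure an analysis run
#'
#' Bundles everything [run_pipeline()] needs: either file inputs (per-locus
#' aligned FASTA plus a metadata table) or a [simulation_config()], the
#' distance settings, the grouping level, the locus combinations to score,
#' and the output directory.
#'
#' @param fasta Named character vector/list of per-locus FASTA paths
#'   (names are locus names); ignored when `simulation` is given.
#' @param metadata Path to the metadata TSV/CSV; ignored when
#'   `simulation` is given.
#' @param simulation Optional [simulation_config()]; when present the
#'   dataset is simulated instead of read.
#' @param group_by Metadata column for the within-group species pairs.
#' @param group_alias Optional named vector merging group labels (see
#'   [interspecific_pairs()]).
#' @param metric `"p"` or `"k2p"`.
#' @param min_sites Minimum comparable sites per pair.
#' @param loci Loci to analyse; default all available.
#' @param combinations List of character vectors of loci to score as
#'   combinations; `NULL` (default) scores every single locus, every
#'   locus pair, and the full locus set.
#' @param combine_rule `"union"` or `"concatenation"`.
#' @param bonferroni_m Number of comparisons for the Bonferroni
#'   correction; default = number of locus pairs tested.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @param strict Treat dataset consistency issues as fatal.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(fasta = NULL, metadata = NULL, simulation = NULL,
                       group_by = "group", group_alias = NULL,
                       metric = c("p", "k2p"), min_sites = 1,
                       loci = NULL, combinations = NULL,
                       combine_rule = c("union", "concatenation"),
                       bonferroni_m = NULL, out_dir = NULL,
                       strict = FALSE) {
  metric <- match.arg(metric)
  combine_rule <- match.arg(combine_rule)
  if (is.null(simulation)) {
    if (is.null(fasta) || is.null(metadata)) {
      stop("either 'simulation' or both 'fasta' and 'metadata' are required",
           call. = FALSE)
    }
    if (is.null(names(fasta)) || any(!nzchar(names(fasta)))) {
      stop("'fasta' must be named by locus", call. = FALSE)
    }
  } else {
    stopifnot(inherits(simulation, "simulation_config"))
  }
  structure(
    list(fasta = fasta, metadata = metadata, simulation = simulation,
         group_by = group_by, group_alias = group_alias, metric = metric,
         min_sites = min_sites, loci = loci, combinations = combinations,
         combine_rule = combine_rule, bonferroni_m = bonferroni_m,
         out_dir = out_dir, strict = strict),
    class = "run_config"
  )
}

#' Run the full barcode-evaluation pipeline
#'
#' Loads (or simulates) the dataset, validates it, computes per-locus
#' distance tables, and produces the three deliverables: the mean
#' interspecific divergence table (per group and pooled), the matched
#' species-pair tables with signed-rank comparison statistics for every
#' locus pair, and the species-discrimination success-rate matrix for
#' single loci and locus combinations.  All outputs are deterministic
#' given the inputs (and, for simulated data, the seed in the simulation
#' config).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `alignments`, `metadata`, `validation`,
#'   `dist_tables`, `pair_table`, `mean_divergence`, `locus_comparisons`,
#'   `matched` (list of matched tables per locus pair), `discrimination`
#'   (list of `"discrimination_result"`), `success_rates` and `manifest`.
#'   When `config$out_dir` is set, the tables are also written there as
#'   TSV/CSV plus a `manifest.yaml`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$simulation)) {
    sim <- simulate_dataset(config$simulation)
    alignments <- sim$alignments
    metadata <- sim$metadata
  } else {
    alignments <- lapply(names(config$fasta), function(locus) {
      read_fasta_alignment(config$fasta[[locus]], locus_name = locus)
    })
    names(alignments) <- names(config$fasta)
    metadata <- read_metadata(config$metadata)
  }
  loci <- config$loci %||% names(alignments)
  alignments <- alignments[loci]

  validation <- validate_dataset(alignments, metadata)
  fatal <- validation$issues$type %in%
    c("sample_not_in_metadata", "sample_no_sequence")
  if (config$strict && any(fatal)) {
    stop(paste(c("dataset validation failed:",
                 validation$issues$message[fatal]), collapse = "\n  "),
         call. = FALSE)
  }
  log_stage("validate", sprintf("samples=%d loci=%d issues=%d",
                                nrow(metadata), length(loci),
                                nrow(validation$issues)))

  dist_tables <- lapply(alignments, distance_matrix,
                        metric = config$metric,
                        min_sites = config$min_sites)
  log_stage("distances", sprintf("loci=%d metric=%s", length(loci),
                                 config$metric))

  pair_table <- species_pair_table(dist_tables, metadata,
                                   group_by = config$group_by,
                                   group_alias = config$group_alias)
  groups <- unique(pair_table$group)
  mean_div <- do.call(rbind, lapply(loci, function(locus) {
    rows <- lapply(c(groups, "(pooled)"), function(g) {
      gg <- if (g == "(pooled)") NULL else g
      vals <- if (is.null(gg)) pair_table[[locus]] else
        pair_table[[locus]][pair_table$group == gg]
      data.frame(locus = locus, group = g,
                 mean_divergence = mean_divergence(pair_table, locus, gg),
                 n_pairs = sum(!is.na(vals)), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  log_stage("partition", sprintf("species_pairs=%d groups=%d",
                                 nrow(pair_table), length(groups)))

  locus_comparisons <- NULL
  matched <- list()
  if (length(loci) >= 2) {
    combos <- utils::combn(loci, 2)
    m <- config$bonferroni_m %||% ncol(combos)
    locus_comparisons <- compare_loci(pair_table, loci, m = m)
    for (k in seq_len(ncol(combos))) {
      key <- sprintf("%s_vs_%s", combos[2, k], combos[1, k])
      matched[[key]] <- matched_pairs(pair_table, combos[1, k],
                                      combos[2, k])
    }
    log_stage("compare", sprintf("locus_pairs=%d bonferroni_m=%d",
                                 ncol(combos), m))
  }

  combos_to_score <- config$combinations %||% default_combinations(loci)
  discrimination <- lapply(combos_to_score, function(set) {
    species_discrimination(dist_tables, metadata, loci = set,
                           combine_rule = if (length(set) == 1) "union" else
                             config$combine_rule,
                           alignments = alignments,
                           metric = config$metric,
                           min_sites = config$min_sites)
  })
  success_rates <- success_rate_table(discrimination)
  log_stage("discriminate", sprintf("locus_sets=%d species=%d",
                                    length(discrimination),
                                    discrimination[[1]]$n_species))

  manifest <- list(
    package = as.character(utils::packageVersion("fernbarcode")),
    metric = config$metric, min_sites = config$min_sites,
    group_by = config$group_by, combine_rule = config$combine_rule,
    loci = loci,
    n_samples = nrow(metadata),
    n_species = length(unique(metadata$species)),
    n_species_pairs = nrow(pair_table),
    simulation = if (!is.null(config$simulation))
      config_to_list(config$simulation) else NULL,
    fasta = if (!is.null(config$fasta)) as.list(config$fasta) else NULL,
    metadata_file = config$metadata
  )

  result <- list(alignments = alignments, metadata = metadata,
                 validation = validation, dist_tables = dist_tables,
                 pair_table = pair_table, mean_divergence = mean_div,
                 locus_comparisons = locus_comparisons, matched = matched,
                 discrimination = discrimination,
                 success_rates = success_rates, manifest = manifest)

  if (!is.null(config$out_dir)) {
    write_report_bundle(result, config$out_dir)
  }
  invisible(result)
}

default_combinations <- function(loci) {
  singles <- as.list(loci)
  if (length(loci) < 2) return(singles)
  pairs <- utils::combn(loci, 2, simplify = FALSE)
  full <- if (length(loci) > 2) list(loci) else list()
  c(singles, pairs, full)
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$mean_divergence, "mean_divergence.tsv")
  wt(result$pair_table, "species_pairs.tsv")
  if (!is.null(result$locus_comparisons)) {
    wt(result$locus_comparisons, "locus_comparisons.tsv")
  }
  for (key in names(result$matched)) {
    scatter_export(result$matched[[key]],
                   file.path(out_dir, sprintf("scatter_%s.csv", key)))
  }
  wt(result$success_rates, "discrimination_rates.tsv")
  verdicts <- do.call(rbind, lapply(result$discrimination, function(r) {
    cbind(loci = paste(r$loci, collapse = "+"), r$per_pair,
          stringsAsFactors = FALSE)
  }))
  wt(verdicts, "discrimination_pairs.tsv")
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Export a matched species-pair table for plotting
#'
#' Writes the machine-readable form of a locus-versus-locus scatter panel:
#' columns `group`, `species_a`, `species_b`, `d_x`, `d_y`, with the
#' distances rounded to six decimals.
#'
#' @param matched A [matched_pairs()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
scatter_export <- function(matched, path) {
  out <- matched[c("group", "species_a", "species_b", "d_x", "d_y")]
  out$d_x <- round(out$d_x, 6)
  out$d_y <- round(out$d_y, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

log_stage <- function(stage, info) {
  message(sprintf("[fernbarcode] stage=%s %s", stage, info))
}
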