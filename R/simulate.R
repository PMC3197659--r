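#' Specify one simulated locus
#'
#' @param name Locus name (used for file names and table columns).
#' @param length Alignment length in bp.
#' @param rate Expected substitutions per site from root to tip (tree
#'   depth is normalized to 1, so `rate` is directly the root-to-tip
#'   divergence).
#' @param kappa Transition/transversion ratio of the substitution process
#'   (expected transitions over expected transversions; 0.5 corresponds to
#'   the Jukes-Cantor special case).  Default 1.5, a typical plastid
#'   value.
#' @param clade_multiplier Optional rate multiplier in `(0, 1]` applied to
#'   every branch inside a designated clade (and its stem), emulating the
#'   reduced substitution rate of loci translocated into the plastid
#'   inverted repeat.
#' @param clade_tips Character vector of tip labels whose most recent
#'   common ancestor defines the slowed clade; alternatively give
#'   `clade_fraction`.
#' @param clade_fraction Pick, at simulation time, the smallest clade
#'   containing at least this fraction of the species as the slowed clade.
#' @return An object of class `"locus_spec"`.
#' @export
locus_spec <- function(name, length, rate, kappa = 1.5,
                       clade_multiplier = NULL, clade_tips = NULL,
                       clade_fraction = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            length >= 1, rate >= 0, kappa > 0)
  if (!is.null(clade_multiplier)) {
    if (clade_multiplier <= 0 || clade_multiplier > 1) {
      stop("clade_multiplier must be in (0, 1]", call. = FALSE)
    }
    if (is.null(clade_tips) && is.null(clade_fraction)) {
      stop("clade_multiplier needs clade_tips or clade_fraction",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, length = as.integer(length), rate = rate,
         kappa = kappa, clade_multiplier = clade_multiplier,
         clade_tips = clade_tips, clade_fraction = clade_fraction),
    class = "locus_spec"
  )
}

# Four plastid-like loci with strongly unequal rates; the trnH-psbA
# analogue is sharply slowed inside a clade covering most species.
default_locus_set <- function() {
  list(
    locus_spec("matK_like",      length = 1200, rate = 0.20),
    locus_spec("rbcL_like",      length = 1300, rate = 0.07),
    locus_spec("trnH_psbA_like", length = 700,  rate = 0.15,
               clade_multiplier = 0.25, clade_fraction = 0.8),
    locus_spec("trnL_F_like",    length = 900,  rate = 0.22)
  )
}

#' Configure a simulated multi-locus dataset
#'
#' The defaults emulate a densely sampled focal genus: ~20 species on a
#' Yule tree, most species with 2-3 individuals and a few singletons, four
#' plastid loci with strongly unequal substitution rates, one locus slowed
#' 4-fold within a clade spanning most of the genus, two species complexes
#' of four species each sharing a single haplotype at every locus, a small
#' per-sample chance of missing a locus, and sparse alignment gaps.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_species Number of species (tree tips), `>= 2`.
#' @param max_individuals Upper bound on individuals per non-singleton
#'   species (sampled uniformly from `2:max_individuals`).
#' @param singleton_fraction Fraction of species represented by a single
#'   individual.
#' @param birth_rate Yule birth rate for the species tree.
#' @param tree Optional fixed tree (`phylo` or newick string); overrides
#'   the Yule simulation.  Depth is normalized to 1.
#' @param intraspecific_scale Star-shaped within-species divergence, as a
#'   fraction of tree depth (each individual diverges from its species
#'   haplotype by `intraspecific_scale * rate` expected substitutions per
#'   site).
#' @param loci List of [locus_spec()] objects.
#' @param complex_groups List of disjoint character vectors of species
#'   names; each group is forced to share one haplotype at all loci
#'   (polyploid/hybrid species complexes that plastid barcodes cannot
#'   separate).
#' @param missing_locus_rate Per (sample, locus) probability that the
#'   sample is absent from that locus's alignment.
#' @param gap_rate Expected fraction of gapped sites per sequence; gaps
#'   are inserted as short deletions.
#' @param group Group label written to the metadata `group` column.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 42L,
                              n_species = 20,
                              max_individuals = 3,
                              singleton_fraction = 0.1,
                              birth_rate = 1,
                              tree = NULL,
                              intraspecific_scale = 0.01,
                              loci = default_locus_set(),
                              complex_groups = list(
                                sprintf("sp%02d", 1:4),
                                sprintf("sp%02d", 5:8)),
                              missing_locus_rate = 0.05,
                              gap_rate = 0.01,
                              group = "FocalGenus") {
  stopifnot(n_species >= 2, max_individuals >= 1,
            singleton_fraction >= 0, singleton_fraction <= 1,
            birth_rate > 0, intraspecific_scale >= 0,
            missing_locus_rate >= 0, missing_locus_rate < 1,
            gap_rate >= 0, gap_rate < 1)
  if (length(loci) < 1 ||
      !all(vapply(loci, inherits, logical(1), "locus_spec"))) {
    stop("'loci' must be a nonempty list of locus_spec objects",
         call. = FALSE)
  }
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(names(loci))) {
    stop("duplicate locus names", call. = FALSE)
  }
  if (length(complex_groups)) {
    all_members <- unlist(complex_groups)
    if (anyDuplicated(all_members)) {
      stop("complex_groups must be disjoint", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         max_individuals = as.integer(max_individuals),
         singleton_fraction = singleton_fraction,
         birth_rate = birth_rate, tree = tree,
         intraspecific_scale = intraspecific_scale, loci = loci,
         complex_groups = complex_groups,
         missing_locus_rate = missing_locus_rate, gap_rate = gap_rate,
         group = group),
    class = "simulation_config"
  )
}

#' Simulate an ultrametric Yule species tree with depth 1
#'
#' @param n_species Number of tips (`>= 2`).
#' @param birth_rate Yule birth rate.
#' @return A `phylo` tree with tips `sp01`, `sp02`, ... and root-to-tip
#'   depth normalized to 1.  Uses the session RNG; seed it for
#'   reproducibility.
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Smallest clade covering at least a fraction of the species
#'
#' @param tree A `phylo` tree.
#' @param fraction Minimum fraction of tips the clade must contain.
#' @return Character vector of tip labels of the selected clade (the one
#'   with the fewest tips among those meeting the threshold; the root
#'   qualifies as a last resort).
#' @export
select_clade <- function(tree, fraction) {
  n <- length(tree$tip.label)
  need <- ceiling(fraction * n)
  counts <- tabulate_tip_counts(tree)
  internal <- (n + 1):(n + tree$Nnode)
  eligible <- internal[counts[internal] >= need]
  node <- eligible[which.min(counts[eligible])]
  tree$tip.label[clade_tip_indices(tree, node)]
}

# Number of descendant tips under every node (tips count themselves).
tabulate_tip_counts <- function(tree) {
  n <- length(tree$tip.label)
  counts <- integer(n + tree$Nnode)
  counts[seq_len(n)] <- 1L
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    counts[edges[k, 1]] <- counts[edges[k, 1]] + counts[edges[k, 2]]
  }
  counts
}

# Tip indices descending from `node` (including `node` if it is a tip).
clade_tip_indices <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  todo <- node
  tips <- integer()
  while (length(todo)) {
    children <- tree$edge[tree$edge[, 1] %in% todo, 2]
    tips <- c(tips, children[children <= n])
    todo <- children[children > n]
  }
  sort(tips)
}

# All nodes (internal and tip) in the clade rooted at the MRCA of `tips`,
# including the MRCA itself, so the stem branch is part of the clade.
clade_node_set <- function(tree, tips) {
  n <- length(tree$tip.label)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop(sprintf("clade tips not in tree: %s",
                 paste(tips[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  if (length(idx) == 1) return(idx)
  mrca <- ape::getMRCA(tree, idx)
  nodes <- mrca
  todo <- mrca
  while (length(todo)) {
    children <- tree$edge[tree$edge[, 1] %in% todo, 2]
    nodes <- c(nodes, children)
    todo <- children[children > n]
  }
  nodes
}

# K2P transition-probability matrix for expected divergence d (subs/site)
# and ts/tv ratio kappa (= alpha / (2 beta)).  States 1..4 = A,C,G,T with
# transition partners A<->G, C<->T.
pmat_k2p <- function(d, kappa) {
  k <- 2 * kappa                       # alpha / beta
  e1 <- exp(-4 * d / (k + 2))
  e2 <- exp(-2 * d * (k + 1) / (k + 2))
  p_tv <- (1 - e1) / 4
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_same <- 1 - p_ts - 2 * p_tv
  partner <- c(3L, 4L, 1L, 2L)
  P <- matrix(p_tv, 4, 4)
  diag(P) <- p_same
  P[cbind(1:4, partner)] <- p_ts
  P
}

# Evolve integer-coded sequence along one branch of length d (subs/site).
mutate_codes <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  cum <- t(apply(pmat_k2p(d, kappa), 1, cumsum))
  cum[, 4] <- 1                        # guard rounding
  u <- stats::runif(length(codes))
  5L - rowSums(u < cum[codes, , drop = FALSE])
}

#' Evolve one locus along a species tree
#'
#' Simulates a root sequence uniform over A/C/G/T, evolves it along the
#' (depth-1) tree under a continuous-time K2P substitution process with
#' the locus rate (multiplied by `clade_multiplier` on branches inside the
#' designated clade, including its stem), producing one haplotype per
#' species.  Species in a complex group are then overwritten with the
#' haplotype of the group's first member.  Individuals diverge from their
#' species haplotype in star fashion by `intraspecific_scale * rate`
#' expected substitutions per site (rate includes the clade multiplier for
#' tips inside the slowed clade).  Finally, short deletions are placed at
#' `gap_rate`.
#'
#' @param tree `phylo` species tree, depth normalized to 1, tips = species.
#' @param spec A [locus_spec()].
#' @param metadata Optional data frame with `sample_id` and `species`
#'   defining the individuals; default one individual per species, sample
#'   ids equal to the tip labels.
#' @param intraspecific_scale,complex_groups,gap_rate See
#'   [simulation_config()].
#' @return A list with `alignment` (a [locus_alignment()]), `truth` (data
#'   frame of per-branch expected and realized substitution counts with a
#'   `slowed` flag) and `clade_tips` (tips of the slowed clade, or `NULL`).
#'   Uses the session RNG.
#' @export
evolve_locus <- function(tree, spec, metadata = NULL,
                         intraspecific_scale = 0,
                         complex_groups = list(), gap_rate = 0) {
  stopifnot(inherits(spec, "locus_spec"), inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  L <- spec$length

  clade_tips <- NULL
  slow_nodes <- integer()
  if (!is.null(spec$clade_multiplier)) {
    clade_tips <- spec$clade_tips %||% select_clade(tree, spec$clade_fraction)
    slow_nodes <- clade_node_set(tree, clade_tips)
  }

  ord <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", n + tree$Nnode)
  root <- n + 1L
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  truth <- data.frame(
    locus = character(), parent = integer(), child = integer(),
    length = numeric(), expected_subs = numeric(),
    realized_subs = integer(), slowed = logical(),
    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    slowed <- child %in% slow_nodes
    mult <- if (slowed) spec$clade_multiplier else 1
    d <- ord$edge.length[k] * spec$rate * mult
    seqs[[child]] <- mutate_codes(seqs[[par]], d, spec$kappa)
    truth[nrow(truth) + 1L, ] <- list(
      spec$name, par, child, ord$edge.length[k], d * L,
      sum(seqs[[child]] != seqs[[par]]), slowed)
  }
  haplotypes <- do.call(rbind, seqs[seq_len(n)])
  rownames(haplotypes) <- tree$tip.label

  for (grp in complex_groups) {
    grp <- intersect(grp, tree$tip.label)
    if (length(grp) > 1) {
      shared <- haplotypes[grp[1], ]
      for (sp in grp) haplotypes[sp, ] <- shared
    }
  }

  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = tree$tip.label,
                           species = tree$tip.label,
                           stringsAsFactors = FALSE)
  }
  tip_mult <- ifelse(tree$tip.label %in% clade_tips,
                     spec$clade_multiplier %||% 1, 1)
  names(tip_mult) <- tree$tip.label
  mat <- matrix(0L, nrow(metadata), L,
                dimnames = list(metadata$sample_id, NULL))
  for (i in seq_len(nrow(metadata))) {
    sp <- metadata$species[i]
    if (!sp %in% rownames(haplotypes)) {
      stop(sprintf("species '%s' is not a tree tip", sp), call. = FALSE)
    }
    d_i <- intraspecific_scale * spec$rate * tip_mult[sp]
    mat[i, ] <- mutate_codes(haplotypes[sp, ], d_i, spec$kappa)
  }

  chars <- decode_residues(mat)
  rownames(chars) <- metadata$sample_id
  if (gap_rate > 0) {
    for (i in seq_len(nrow(chars))) {
      n_events <- stats::rpois(1, gap_rate * L / 3)
      for (e in seq_len(n_events)) {
        start <- sample.int(L, 1)
        len <- sample.int(5L, 1)
        chars[i, start:min(L, start + len - 1)] <- "-"
      }
    }
  }
  list(alignment = locus_alignment(spec$name, chars),
       truth = truth, clade_tips = clade_tips)
}

#' Simulate a complete multi-locus dataset in memory
#'
#' Orchestrates [simulate_species_tree()] and [evolve_locus()] for every
#' configured locus, assigns individuals to species, drops samples from
#' loci at `missing_locus_rate` (each locus always retains at least two
#' samples) and records a truth log sufficient for parameter-recovery
#' checks.
#'
#' @param config A [simulation_config()].
#' @return A list with `alignments` (named list of [locus_alignment()]),
#'   `metadata` (data frame `sample_id`, `species`, `group`,
#'   `individual`), `tree` (`phylo`), and `truth` (list of data frames:
#'   `edges`, `missing`, `complexes`, `clades`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- simulate_species_tree(config$n_species, config$birth_rate)
  } else {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  species <- tree$tip.label
  n <- length(species)

  stray <- setdiff(unlist(config$complex_groups), species)
  if (length(stray)) {
    stop(sprintf("complex_groups name unknown species: %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }

  n_singleton <- round(config$singleton_fraction * n)
  singletons <- if (n_singleton > 0) sample(species, n_singleton) else
    character()
  counts <- stats::setNames(integer(n), species)
  counts[singletons] <- 1L
  rest <- setdiff(species, singletons)
  counts[rest] <- if (config$max_individuals <= 2) {
    rep(min(2L, config$max_individuals), length(rest))
  } else {
    sample(2:config$max_individuals, length(rest), replace = TRUE)
  }
  metadata <- do.call(rbind, lapply(species, function(sp) {
    data.frame(sample_id = sprintf("%s_i%d", sp, seq_len(counts[sp])),
               species = sp, group = config$group,
               individual = sprintf("i%d", seq_len(counts[sp])),
               stringsAsFactors = FALSE)
  }))

  alignments <- list()
  edges <- list()
  missing <- list()
  clades <- list()
  for (locus in names(config$loci)) {
    spec <- config$loci[[locus]]
    ev <- evolve_locus(tree, spec, metadata = metadata,
                       intraspecific_scale = config$intraspecific_scale,
                       complex_groups = config$complex_groups,
                       gap_rate = config$gap_rate)
    aln <- ev$alignment
    if (config$missing_locus_rate > 0) {
      drop <- which(stats::runif(nrow(metadata)) < config$missing_locus_rate)
      max_drop <- nrow(metadata) - 2L
      if (length(drop) > max_drop) drop <- drop[seq_len(max_drop)]
      if (length(drop)) {
        missing[[length(missing) + 1L]] <- data.frame(
          locus = locus, sample_id = metadata$sample_id[drop],
          stringsAsFactors = FALSE)
        keep <- setdiff(seq_len(nrow(metadata)), drop)
        aln <- locus_alignment(locus,
                               aln$matrix[keep, , drop = FALSE])
      }
    }
    alignments[[locus]] <- aln
    edges[[locus]] <- ev$truth
    if (!is.null(ev$clade_tips)) {
      clades[[length(clades) + 1L]] <- data.frame(
        locus = locus, tip = ev$clade_tips,
        multiplier = spec$clade_multiplier, stringsAsFactors = FALSE)
    }
  }

  complexes <- if (length(config$complex_groups)) {
    do.call(rbind, lapply(seq_along(config$complex_groups), function(g) {
      data.frame(complex = sprintf("complex%d", g),
                 species = config$complex_groups[[g]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(complex = character(), species = character(),
               stringsAsFactors = FALSE)
  }

  list(
    alignments = alignments,
    metadata = metadata,
    tree = tree,
    truth = list(
      edges = do.call(rbind, c(edges, list(make.row.names = FALSE))),
      missing = if (length(missing)) do.call(rbind, missing) else
        data.frame(locus = character(), sample_id = character(),
                   stringsAsFactors = FALSE),
      complexes = complexes,
      clades = if (length(clades)) do.call(rbind, clades) else
        data.frame(locus = character(), tip = character(),
                   multiplier = numeric(), stringsAsFactors = FALSE)
    )
  )
}

#' Write a simulated dataset to disk
#'
#' Writes one aligned FASTA per locus, the sample metadata TSV, the truth
#' log TSVs, the tree (newick) and an echo of the configuration (YAML).
#' With a fixed seed the directory contents are byte-identical across
#' runs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list from [simulate_dataset()] with a `files`
#'   element added.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop(sprintf("output directory is not writable: %s", out_dir),
         call. = FALSE)
  }
  sim <- simulate_dataset(config)
  files <- character()
  for (locus in names(sim$alignments)) {
    f <- file.path(out_dir, paste0(locus, ".fasta"))
    write_fasta_alignment(sim$alignments[[locus]], f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "metadata.tsv")
  utils::write.table(sim$metadata, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  for (nm in names(sim$truth)) {
    f <- file.path(out_dir, sprintf("truth_%s.tsv", nm))
    utils::write.table(sim$truth[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "tree.nwk")
  ape::write.tree(sim$tree, f)
  files <- c(files, f)
  f <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(config), f)
  files <- c(files, f)
  sim$files <- files
  invisible(sim)
}

# Serializable form of a simulation_config (tree as newick).
config_to_list <- function(config) {
  out <- unclass(config)
  if (inherits(out$tree, "phylo")) out$tree <- ape::write.tree(out$tree)
  out$loci <- lapply(out$loci, function(sp) {
    sp <- unclass(sp)
    sp[!vapply(sp, is.null, logical(1))]
  })
  out
}

#' Read a simulation configuration from YAML
#'
#' Accepts the schema written by [generate_dataset()]: top-level scalars
#' mirroring the [simulation_config()] arguments, `loci` as a named list
#' of [locus_spec()] argument lists, and `tree` as a newick string.
#'
#' @param path Path to the YAML file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$loci)) {
    raw$loci <- lapply(raw$loci, function(args) do.call(locus_spec, args))
    names(raw$loci) <- NULL
  }
  do.call(simulation_config, raw)
}
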