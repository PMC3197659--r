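test_that("Yule species trees are ultrametric with unit depth", {
  set.seed(501)
  tr <- simulate_species_tree(2)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)

  tr <- simulate_species_tree(12)
  expect_equal(length(tr$tip.label), 12)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)

  set.seed(77)
  a <- ape::write.tree(simulate_species_tree(10))
  set.seed(77)
  b <- ape::write.tree(simulate_species_tree(10))
  expect_identical(a, b)

  expect_error(simulate_species_tree(1), ">= 2")
})

test_that("select_clade picks the smallest clade over the threshold", {
  set.seed(502)
  tr <- simulate_species_tree(15)
  tips <- select_clade(tr, 0.8)
  expect_gte(length(tips), ceiling(0.8 * 15))
  expect_true(all(tips %in% tr$tip.label))
  # every other eligible clade is at least as large
  counts <- fernbarcode:::tabulate_tip_counts(tr)
  internal <- 16:(15 + tr$Nnode)
  eligible <- counts[internal][counts[internal] >= ceiling(0.8 * 15)]
  expect_equal(length(tips), min(eligible))
})

test_that("zero rate propagates the root sequence everywhere", {
  set.seed(503)
  tr <- simulate_species_tree(6)
  ev <- evolve_locus(tr, locus_spec("flat", 150, rate = 0))
  tab <- distance_matrix(ev$alignment)
  expect_true(all(tab$d == 0))
  expect_true(all(ev$truth$realized_subs == 0))
})

test_that("realized divergence matches the closed-form expectation", {
  # cherry of depth 1, rate r per lineage: total path 2r; with kappa=0.5
  # the process is Jukes-Cantor, E[p] = 3/4 (1 - exp(-4 * 2r / 3))
  set.seed(504)
  r <- 0.15
  tr <- ape::read.tree(text = "(sp01:1,sp02:1);")
  spec <- locus_spec("jc", 400, rate = r, kappa = 0.5)
  ps <- replicate(200, {
    ev <- evolve_locus(tr, spec)
    p_distance(compare_pair(ev$alignment$matrix[1, ],
                            ev$alignment$matrix[2, ]))
  })
  expected <- 0.75 * (1 - exp(-4 * 2 * r / 3))
  se <- stats::sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("clade rate multipliers slow within-clade branches", {
  set.seed(505)
  tr <- simulate_species_tree(20)
  tips <- select_clade(tr, 0.6)
  spec <- locus_spec("slow", 800, rate = 0.3, clade_multiplier = 0.25,
                     clade_tips = tips)
  ev <- evolve_locus(tr, spec)
  # per-branch realized substitutions per unit length, slowed vs not
  tt <- ev$truth[ev$truth$length > 0.02, ]
  rate_in <- sum(tt$realized_subs[tt$slowed]) /
    sum(tt$length[tt$slowed])
  rate_out <- sum(tt$realized_subs[!tt$slowed]) /
    sum(tt$length[!tt$slowed])
  expect_lt(rate_in, rate_out / 2)
})

test_that("simulated datasets honour the configuration", {
  cfg <- simulation_config(
    seed = 9, n_species = 10, max_individuals = 3,
    singleton_fraction = 0.2, intraspecific_scale = 0,
    loci = list(locus_spec("A", 200, 0.2), locus_spec("B", 150, 0.05)),
    complex_groups = list(c("sp01", "sp02", "sp03")),
    missing_locus_rate = 0, gap_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_named(sim$alignments, c("A", "B"))
  expect_equal(length(unique(sim$metadata$species)), 10)
  expect_equal(sum(table(sim$metadata$species) == 1), 2)  # 20% singletons

  # complex members share one haplotype at every locus (noise-free)
  for (aln in sim$alignments) {
    ids <- sim$metadata$sample_id[sim$metadata$species %in%
                                  c("sp01", "sp02", "sp03")]
    rows <- aln$matrix[intersect(ids, aln$sample_ids), , drop = FALSE]
    expect_equal(nrow(unique(rows)), 1)
  }

  # byte-identical regeneration under a fixed seed
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("missing-locus dropout is approximately binomial", {
  cfg <- simulation_config(
    seed = 10, n_species = 25, max_individuals = 3,
    singleton_fraction = 0,
    loci = list(locus_spec("A", 60, 0.1), locus_spec("B", 60, 0.1),
                locus_spec("C", 60, 0.1), locus_spec("D", 60, 0.1)),
    complex_groups = list(), missing_locus_rate = 0.2, gap_rate = 0)
  sim <- simulate_dataset(cfg)
  n_cells <- nrow(sim$metadata) * length(sim$alignments)
  n_missing <- n_cells - sum(vapply(sim$alignments, function(a)
    length(a$sample_ids), integer(1)))
  # within 4 binomial standard deviations of the 20% target
  expect_lt(abs(n_missing / n_cells - 0.2),
            4 * sqrt(0.2 * 0.8 / n_cells))
  expect_equal(nrow(sim$truth$missing), n_missing)
})

test_that("gaps appear at roughly the configured density", {
  cfg <- simulation_config(
    seed = 11, n_species = 10, singleton_fraction = 0,
    loci = list(locus_spec("A", 500, 0.1)),
    complex_groups = list(), missing_locus_rate = 0, gap_rate = 0.05)
  sim <- simulate_dataset(cfg)
  frac <- mean(sim$alignments$A$matrix == "-")
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
})

test_that("configs validate and round-trip through YAML", {
  expect_error(simulation_config(n_species = 1), "n_species")
  expect_error(simulation_config(complex_groups = list("sp01", "sp01")),
               "disjoint")
  expect_error(locus_spec("x", 100, 0.1, clade_multiplier = 2),
               "multiplier")
  expect_error(locus_spec("x", 100, 0.1, clade_multiplier = 0.5),
               "clade_tips or clade_fraction")

  cfg <- simulation_config(seed = 3, n_species = 6,
                           complex_groups = list(c("sp01", "sp02")))
  d <- file.path(tempdir(), "cfg_roundtrip")
  generate_dataset(cfg, d)
  cfg2 <- read_simulation_config(file.path(d, "config.yaml"))
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(names(cfg2$loci), names(cfg$loci))
  expect_equal(cfg2$loci[[3]]$clade_multiplier,
               cfg$loci[[3]]$clade_multiplier)
  # and the regenerated dataset is identical
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg2)
  expect_identical(sim1$alignments$matK_like$matrix,
                   sim2$alignments$matK_like$matrix)
})
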