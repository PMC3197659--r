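test_that("the pairwise rule applies strict inequalities to min/max", {
  L <- 1000
  base <- strrep("ACGT", L / 4)
  mut <- function(s, at) {
    v <- chars(s)
    v[at] <- ifelse(v[at] == "A", "G", "A")
    paste(v, collapse = "")
  }
  # shared haplotypes -> never distinguished
  aln <- aln_from_strings(list(a1 = base, b1 = base))
  md <- md_from_samples(c("a1", "b1"), c("spA", "spB"))
  tab <- distance_matrix(aln)
  intra <- intraspecific_summary(tab, md)
  expect_equal(pair_distinguished("spA", "spB", tab, intra, md),
               "not_distinguished")

  # fixed distinct haplotypes, zero intraspecific variation
  aln <- aln_from_strings(list(a1 = base, a2 = base, b1 = mut(base, 1)))
  md <- md_from_samples(c("a1", "a2", "b1"), c("spA", "spA", "spB"))
  tab <- distance_matrix(aln)
  intra <- intraspecific_summary(tab, md)
  expect_equal(pair_distinguished("spA", "spB", tab, intra, md),
               "distinguished")

  # inter min 0.003 <= intra max 0.004 -> fails
  aln <- aln_from_strings(list(
    a1 = base, a2 = mut(base, c(1, 5, 9, 13)),          # intra = 0.004
    b1 = mut(base, c(21, 25, 29))))                     # inter(a1,b1)=0.003
  md <- md_from_samples(c("a1", "a2", "b1"), c("spA", "spA", "spB"))
  tab <- distance_matrix(aln)
  intra <- intraspecific_summary(tab, md)
  expect_equal(intra$max_intra[intra$species == "spA"], 0.004)
  expect_equal(min(tab$d["b1", c("a1", "a2")]), 0.003)
  expect_equal(pair_distinguished("spA", "spB", tab, intra, md),
               "not_distinguished")

  expect_error(pair_distinguished("spZ", "spB", tab, intra, md),
               "unknown species")
})

test_that("union combination needs every pair of a species covered", {
  # locus A separates only (sp1, sp2); locus B only (sp1, sp3); the pair
  # (sp2, sp3) is masked at both loci by intraspecific variation.  Only
  # sp1 has all of its pairs covered, so the union discriminates sp1
  # alone.
  L <- 400
  base <- strrep("ACGT", L / 4)
  mut <- function(s, at) {
    v <- chars(s)
    v[at] <- ifelse(v[at] == "A", "G", "A")
    paste(v, collapse = "")
  }
  alnA <- aln_from_strings(list(s1 = base,
                                s2a = mut(base, 1), s2b = mut(base, 1),
                                s3a = base, s3b = mut(base, c(9, 13))),
                           "A")
  alnB <- aln_from_strings(list(s1 = base,
                                s2a = base, s2b = mut(base, c(17, 21)),
                                s3a = mut(base, 5), s3b = mut(base, 5)),
                           "B")
  md <- md_from_samples(c("s1", "s2a", "s2b", "s3a", "s3b"),
                        c("sp1", "sp2", "sp2", "sp3", "sp3"))
  tabs <- list(A = distance_matrix(alnA), B = distance_matrix(alnB))

  one <- species_discrimination(tabs, md, loci = "A")
  expect_equal(one$per_pair$verdict,
               c("distinguished", "not_distinguished", "not_distinguished"))
  expect_equal(one$success_rate, 0)

  both <- species_discrimination(tabs, md, loci = c("A", "B"),
                                 combine_rule = "union")
  expect_equal(both$discriminated, "sp1")
  expect_equal(both$success_rate, 100 / 3)

  # matches the independent truth-table evaluation
  dmats <- lapply(tabs, `[[`, "d")
  expect_equal(both$success_rate,
               oracle_discrimination(dmats, md, c("A", "B"), "union"))

  # union success never drops when a locus is added
  expect_gte(both$success_rate, one$success_rate)
})

test_that("species-level aggregation yields the expected toy rates", {
  L <- 400
  base <- strrep("ACGT", L / 4)
  mut <- function(s, at) {
    v <- chars(s)
    v[at] <- ifelse(v[at] == "A", "G", "A")
    paste(v, collapse = "")
  }
  # 4 species; sp3 and sp4 share one haplotype -> 2/4 = 50%
  aln <- aln_from_strings(list(s1 = mut(base, 1), s2 = mut(base, 5),
                               s3 = base, s4 = base))
  md <- md_from_samples(sprintf("s%d", 1:4), sprintf("sp%d", 1:4))
  res <- species_discrimination(list(L1 = distance_matrix(aln)), md)
  expect_equal(res$success_rate, 50)
  expect_equal(sort(res$discriminated), c("sp1", "sp2"))
  expect_equal(success_rate_table(res)$success_rate, 50.0)

  # all distinct -> 100; all shared -> 0
  aln100 <- aln_from_strings(list(s1 = mut(base, 1), s2 = mut(base, 5),
                                  s3 = mut(base, 9), s4 = mut(base, 13)))
  expect_equal(species_discrimination(
    list(L1 = distance_matrix(aln100)), md)$success_rate, 100)
  aln0 <- aln_from_strings(list(s1 = base, s2 = base, s3 = base,
                                s4 = base))
  expect_equal(species_discrimination(
    list(L1 = distance_matrix(aln0)), md)$success_rate, 0)
})

test_that("no-data pairs mark both species as non-discriminable", {
  L <- 400
  base <- strrep("ACGT", L / 4)
  mut <- function(s, at) {
    v <- chars(s)
    v[at] <- "G"
    paste(v, collapse = "")
  }
  # sp3 absent from the only locus: its pairs are no-data, so neither
  # sp3 nor its partners can be fully discriminated
  aln <- aln_from_strings(list(s1 = mut(base, 1), s2 = mut(base, 5)))
  md <- md_from_samples(c("s1", "s2", "s3"), c("sp1", "sp2", "sp3"))
  res <- species_discrimination(list(L1 = distance_matrix(aln)), md)
  expect_equal(res$per_pair$verdict[res$per_pair$species_b == "sp3"],
               c("no_data", "no_data"))
  expect_equal(res$success_rate, 0)
})

test_that("concatenation recomputes distances on the joined alignment", {
  set.seed(401)
  for (rep in 1:5) {
    n_sp <- sample(3:5, 1)
    md <- md_from_samples(character(), character())
    ids <- character()
    species <- character()
    for (s in seq_len(n_sp)) {
      k <- sample(1:3, 1)
      ids <- c(ids, sprintf("sp%d_i%d", s, seq_len(k)))
      species <- c(species, rep(sprintf("sp%d", s), k))
    }
    md <- md_from_samples(ids, species)
    alns <- list()
    for (l in c("A", "B")) {
      mat <- do.call(rbind, lapply(seq_along(ids), function(i) {
        random_seq(60, gap_prob = 0.02)
      }))
      rownames(mat) <- ids
      keep <- sort(sample(seq_along(ids), max(2, length(ids) - 1)))
      alns[[l]] <- locus_alignment(l, mat[keep, , drop = FALSE])
    }
    tabs <- lapply(alns, distance_matrix)
    res <- species_discrimination(tabs, md, combine_rule = "concatenation",
                                  alignments = alns)
    expected <- oracle_discrimination(
      NULL, md, c("A", "B"), "concatenation",
      concat_dmat = oracle_concat_dmat(alns, c("A", "B")))
    expect_equal(res$success_rate, expected)
  }
})

test_that("success rate is invariant to sample, label and locus order", {
  set.seed(402)
  cfg <- simulation_config(seed = 11, n_species = 6, max_individuals = 2,
                           singleton_fraction = 0,
                           loci = list(locus_spec("A", 200, 0.15),
                                       locus_spec("B", 200, 0.05)),
                           complex_groups = list(),
                           missing_locus_rate = 0, gap_rate = 0)
  sim <- simulate_dataset(cfg)
  tabs <- lapply(sim$alignments, distance_matrix)
  base <- species_discrimination(tabs, sim$metadata)$success_rate

  # permute rows of each alignment
  tabs2 <- lapply(sim$alignments, function(a) {
    distance_matrix(locus_alignment(a$locus,
      a$matrix[sample(nrow(a$matrix)), , drop = FALSE]))
  })
  expect_equal(species_discrimination(tabs2, sim$metadata)$success_rate,
               base)

  # reverse locus order
  expect_equal(species_discrimination(rev(tabs), sim$metadata)$success_rate,
               base)

  # relabel species consistently
  md3 <- sim$metadata
  md3$species <- chartr("sp", "qx", md3$species)
  expect_equal(species_discrimination(tabs, md3)$success_rate, base)
})

test_that("concatenate_loci pads missing samples with missing data", {
  alnA <- aln_from_strings(list(s1 = "ACGT", s2 = "ACGA"), "A")
  alnB <- aln_from_strings(list(s1 = "TTTT"), "B")
  cc <- concatenate_loci(list(A = alnA, B = alnB))
  expect_equal(cc$length, 8)
  expect_equal(paste(cc$matrix["s2", ], collapse = ""), "ACGA????")
  expect_error(species_discrimination(
    list(A = distance_matrix(alnA)), md_from_samples("s1", "spA"),
    loci = "C"), "no distance table")
})
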