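---
title: "Evaluating DNA barcode loci: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode loci: models, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
each choice was made the way it was.

## The analysis units

The pipeline consumes per-locus aligned multi-FASTA files plus a sample
metadata table (`sample_id`, `species`, `group`, `individual`) and
reduces them in three stages:

1. **Sample-level distances** (`distance_matrix()`): all pairwise
   divergences within a locus alignment.
2. **Species-level records** (`species_pair_table()`,
   `intraspecific_summary()`): interspecific divergences for every
   species pair within a group, matched across loci, and the maximum
   intraspecific distance per species.
3. **Comparisons and verdicts** (`compare_loci()`,
   `species_discrimination()`): signed-rank comparisons of locus
   variability on matched pairs, and the species-discrimination success
   rate per locus or locus combination.

## Distances

**p-distance.** `p = mismatch weight / comparable sites` under
*pairwise deletion*: a column counts for a pair only when neither
sequence has `-` (gap) or `N`/`?`/`X` (missing).  Pairwise deletion —
rather than deleting every gapped column globally — preserves
information for well-sequenced pairs and is the convention of classic
distance software.  The comparison result keeps the comparable-site
count, and any pair with fewer than `min_sites` comparable columns
(default 1) is marked *undefined* (`NA`), never 0: downstream logic must
be able to tell "identical" from "no data", and an undefined distance
propagates as undefined everywhere.

**Ambiguity codes.** A column with an IUPAC ambiguity code in either
row contributes its expected mismatch under uniform, independent
resolution over the compatible states (e.g. `A` vs `R` = 1/2, `W` vs
`S` = 1).  The accumulated ambiguity mass is then apportioned between
transitions and transversions *proportionally to the unambiguous changes
already observed for that pair* (50/50 when there are none).  We read
the "distributed proportionally to unambiguous changes" convention as
applying to ambiguity-code mass across change types; the alternative
reading — fractional counting of gap sites — is rejected because a
p-distance needs a comparable-site denominator, and gap columns are
excluded outright.  On ambiguity-free data (the common case for plastid
barcode alignments) the two readings coincide, and the engine is tested
to agree exactly with `ape::dist.dna` there.

**K2P.** `d = -(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q))`.  When the
argument of either logarithm is non-positive (saturation) the distance
is undefined, again an explicit `NA`.  K2P is provided for
comparability with studies that report it; the locus comparisons and
discrimination default to p.

## Species pairs and intraspecific variation

Species pairs are formed only within a `group` (taxonomic order for
broad comparisons; the whole genus for focal datasets).  Small groups
can be pooled with an alias map (e.g. two orders merged into their
shared class) instead of hard-coding taxon names.  For species with
several individuals the pair divergence is the **mean** over defined
cross-species sample pairs.  The mean-versus-single-representative
choice only affects plotting and mean-divergence tables; discrimination
uses the minimum cross distance, so it is unaffected.  The maximum
intraspecific distance is 0 for singletons by convention — with one
individual there is no evidence of variation, and only the "greater
than zero" clause binds.

## Locus comparison

Matched pairs (both loci defined) feed a Wilcoxon matched-pairs
signed-rank test of `d_y - d_x`.  Zero differences are dropped (the
classic treatment, matching the widely used calculators, rather than
Pratt's method).  With no ties among absolute differences and `n <= 25`
the two-sided p is **exact**: `P(min(S+, S-) <= W_obs)` over all `2^n`
sign assignments, computed by subset-sum counting of the rank-sum
distribution (identical to literal enumeration, which the test suite
performs independently).  Otherwise a normal approximation with midrank
tie correction and a 0.5 continuity correction is used; exact and
approximate p agree within 0.01 for `20 <= n <= 25` in the test suite.
Tests pool species pairs across groups by default — one p-value per
locus pair — with per-group stratification available by filtering the
pair table.  Bonferroni correction uses `m =` the number of locus-pair
comparisons in the run (6 for four loci) and is configurable.

The scatter summaries count pairs **strictly** below the 1:1 line and
strictly above the 2:1 and 4:1 lines; a pair exactly on a line exceeds
nothing, and a pair with `d_x = 0 < d_y` exceeds every line.  All
fractions use the full matched-pair count as denominator, so
`frac_y_lt_x + frac_y_gt_x + ties/n = 1`.

## Species discrimination

A pair of species is *distinguished* at a locus iff the minimum defined
cross-species distance is `> 0` **and** `>` the larger of the two
species' maximum intraspecific distances (strict inequalities; the
minimum enforces the "always" in the rule).  A pair with no defined
cross distance is *no-data*, which marks both species as
non-discriminable — a missing locus cannot demonstrate a barcoding gap.
A species is discriminated only when every one of its pairs is
distinguished, and the success rate is the percentage of species
discriminated (reported to one decimal).

Combinations default to the **union** rule: a pair is distinguished
when at least one constituent locus distinguishes it.  This mirrors the
workflow of feeding per-locus distance matrices to a scoring script, is
monotone (adding a locus never lowers the rate — a property the test
suite enforces), and reproduces the observed pattern that a two-locus
barcode does at least as well as its best member.  **Concatenation**
(distances recomputed on the column-joined alignment, missing samples
padded with `?`) is provided for sensitivity analysis; both are
reported, never silently substituted.

## The simulator

`simulation_config()` describes the generative model:

* **Tree**: Yule (pure-birth) species tree, depth normalized to 1 so a
  locus `rate` reads directly as expected substitutions per site from
  root to tip.
* **Substitutions**: continuous-time K2P process sampled per site from
  the closed-form transition matrix, with `kappa` = expected
  transition/transversion ratio (0.5 reduces to Jukes–Cantor, a case
  the tests exploit: for a cherry of depth 1 and rate *r*, `E[p] = 3/4
  (1 - exp(-8r/3))`, checked within Monte-Carlo error).
* **Clade slowdown**: a locus may carry a rate multiplier in `(0, 1]`
  applied to every branch inside a designated clade *and its stem* —
  the translocation event sits on the stem branch — with the clade
  given by tip labels or picked as the smallest clade covering a target
  fraction of species.
* **Individuals**: star-shaped divergence from the species haplotype by
  `intraspecific_scale * rate` substitutions/site; sufficient for
  max-intraspecific statistics, with no within-species genealogy.
* **Species complexes**: each configured group shares the haplotype of
  its first member at every locus, emulating polyploid/hybrid complexes
  that uniparental plastid barcodes cannot separate.  Because complexes
  of unknown (possibly reticulate) origin need not be clades, the
  shared haplotype may originate outside a slowed clade; this
  realistically dilutes the clade-slowdown signal among
  complex-involved pairs, as the package's own reports show.
* **Gaps and missing loci**: short deletions at an expected per-site
  density `gap_rate` (their only role is to exercise pairwise
  deletion), and per-(sample, locus) dropout at `missing_locus_rate`
  (every locus keeps at least two samples).

Defaults — 20 species, 2–3 individuals with ~10% singletons, loci of
700–1300 bp with root-to-tip rates 0.20/0.07/0.15/0.22 and a 0.25
multiplier on the third locus inside a clade covering ≥ 80% of species,
two 4-species complexes, 5% missing, 1% gaps — emulate a densely
sampled fern genus screened with four plastid markers whose fastest
loci diverge on the order of 20% between species while the IR-slowed
spacer lags several-fold inside the translocated clade.  A fixed seed
yields byte-identical datasets and reports.

What the simulator does **not** model: coalescent genealogies,
recombination, indel evolution (gaps are decorative), codon structure,
alignment error, or the gene-conversion mechanism behind IR rate
suppression.  Passing recovery tests therefore demonstrate that the
pipeline measures what the generative model puts in — rate orderings,
clade-restricted slowdowns, haplotype sharing — not that real data meet
the model's assumptions.

## Numerical choices and degenerate inputs

* Undefined distances are `NA` end to end; they never become zeros.
* `min_sites` defaults to 1 and is exposed because very short overlaps
  give noisy distances.
* Exact signed-rank enumeration is capped at `n = 25` (`2^25`
  assignments via an O(n^3) counting recurrence in exact doubles).
* Alignments with fewer than two sequences give an empty table with a
  warning; empty matched tables error in `ratio_summary()` and warn in
  `matched_pairs()`.
* Residues are uppercased on read, `U` maps to `T`, and `N`/`?`/`X`
  are all missing; `-` is the only gap character.
* Ties on a ratio line or between inter- and intraspecific distances
  fail the respective strict test, by design.

## Problem sizes in the test suite

The validation suite runs 500 random pairs (50–500 bp) against a
per-character oracle; every tie-free sign pattern to `n = 10` plus
`n = 12` spot checks against literal enumeration; 2000 null replicates
at `n = 15` for the size of the exact test; 100 random small datasets
for the discrimination oracle (union and concatenation); 100 seeded
30-species replicates each for rate-ordering recovery (rates
0.20/0.10/0.02) and for the clade-slowdown pattern (multiplier 0.25,
clade ≥ 80% of species, `frac_y_lt_x > 0.9` with adjusted p < 0.05 in
≥ 95 of 100); these sizes keep the full suite within a few minutes
while leaving the acceptance margins comfortably non-marginal.

## Known limitations

* The discrimination rule is distance-based only; tree-based
  (monophyly) or BLAST-style criteria are out of scope.
* No multiple-testing procedures beyond Bonferroni, and no effect
  sizes for the signed-rank comparisons.
* The PHYLIP distance writer emits `NA` for undefined entries, which
  strict PHYLIP parsers may reject; the long TSV dialect is lossless.
* Species entirely missing a locus zero out that locus's success rate
  through no-data pairs; this is the rule's intended behavior, but it
  makes single-locus rates sensitive to sampling completeness.
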