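Package: fernbarcode
Title: Evaluation of Plastid DNA Barcode Loci by Divergence and
    Species Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the utility of candidate DNA barcode loci from
    per-locus sequence alignments: pairwise divergence (uncorrected
    p-distance with pairwise deletion and proportional handling of IUPAC
    ambiguity codes, and Kimura two-parameter distance), matched
    species-pair comparisons of locus variability with exact Wilcoxon
    signed-rank tests and Bonferroni correction, and species-discrimination
    success rates for single loci and locus combinations.  Includes a
    simulator of multi-locus plastid datasets (Kimura two-parameter
    substitution process on a Yule species tree, clade-specific rate
    reduction, species complexes sharing haplotypes, alignment gaps and
    missing loci) so every stage of the pipeline can be exercised and
    validated without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
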