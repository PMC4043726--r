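Package: gametolog
Title: Haplotype Networks and X-Y Gametolog Divergence from Sex-Linked
    Sequence Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for phased two-allele-per-individual
    alignments of sex-linked sequence markers: parses allele labels and
    pairs alleles into diploid genotypes, recodes microsatellite-like
    repeat tracts and large indels into single mutational-step characters,
    collapses haplotypes and builds statistical-parsimony networks under a
    95% connection limit, computes within-individual pairwise nucleotide
    differences (X-Y in males, X-X in females), and tests sex and
    sex-by-region effects with permutation ANOVA. Includes a forward
    simulator of X/Y gametologs under tunable male recombination and
    refugium-versus-expansion demography, with ground truth for
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    graphics,
    igraph,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
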