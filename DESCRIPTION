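Package: matcongruence
Title: Congruence-of-Loci Tests for Clonality in Haploid Fungal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the evolutionary histories of a mating-type-like
    locus, an unrelated protein-coding gene and genome-wide SNPs are coupled
    (clonal reproduction) or decoupled (sexual reproduction) in haploid fungal
    populations such as the arbuscular mycorrhizal fungus Rhizophagus
    irregularis. Provides Tamura 3-parameter and p-distances on alignments,
    depth/support/region filtering and Jaccard distances for biallelic SNP
    matrices, Nei-Gojobori dN/dS with a bootstrap codon-based Z-test, codon
    adaptation index (CAI) with an expected-CAI null, Mantel, PERMANOVA and
    Baker's gamma congruence tests on Ward dendrograms, mating-type and allele
    assignment from partial coding alignments, a haploid Wright-Fisher
    simulator of clonal versus mating-type-constrained sexual populations, and
    a pipeline that turns the three datasets into a machine-readable congruence
    verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
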