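Package: epinet
Title: Genotype Networks, Epistasis Classification and Mutational Path
    Accessibility for Quantitative Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds haplotype (genotype) networks from phenotype-associated
    biallelic loci, classifies every four-cycle ("square") of genotypes as
    showing no, magnitude, simple sign, or reciprocal sign epistasis relative
    to a non-genetic noise threshold estimated from replicate genotypes, and
    measures the fraction of shortest mutational paths to extreme phenotypic
    values that is monotonically accessible. Includes a synthetic GWAS-panel
    generator with planted genetic architectures, column-composition
    randomization null models, network-structure descriptors (betweenness,
    modularity), and phylogenetic tip-distance correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
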