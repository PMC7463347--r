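Package: musselmix
Title: Three-Way Admixture, Introgression and Heterozygosity Analysis for
    Mytilus SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying hybridization among the three European
    mussel species (Mytilus edulis, M. galloprovincialis and M. trossulus)
    from reduced-representation SNP genotypes. Implements a post-genotyping
    quality-control chain for RAD-seq VCFs (genotype-level depth and quality
    masking, site call rate, depth cap, individual missingness, minor allele
    frequency and sliding-window linkage pruning), construction of
    pure-species reference allele-frequency panels with polymorphism
    classification and detection of species-diagnostic fixed differences,
    supervised maximum-likelihood estimation of three-way admixture
    proportions by expectation-maximization on a binomial genotype
    likelihood, population observed heterozygosity and standardized
    multilocus heterozygosity (overall and partitioned by SNP class),
    principal component and Ward clustering ordination with locus-bootstrap
    node support, and an inferential layer of linear and random-intercept
    mixed models with parametric-bootstrap likelihood-ratio tests and
    FDR-corrected environmental correlations. A calibrated synthetic-data
    generator reproduces the statistical structure of a three-species
    hybrid zone so that the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    jsonlite,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
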