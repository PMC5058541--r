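Package: slcsd
Title: Diploid Male Production and Genetic Diversity Under Single-Locus
    Complementary Sex Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying diploid male production (DMP) in haplodiploid
    insects with single-locus complementary sex determination (sl-CSD), built
    around microsatellite surveys of the parasitoid wasp Venturia canescens.
    Provides a mixed-ploidy multilocus genotype data model with GENEPOP
    import/export and "false diploid" pair merging, heterozygosity-based
    ploidy calling with a pedigree-based misclassification probability,
    population diversity statistics for mixed-ploidy samples (unbiased
    heterozygosity, exact Hardy-Weinberg and genotypic linkage tests,
    null-allele EM estimation, rarefied allelic richness, private alleles),
    a nested binomial GLM relating DMP to habitat and genetic diversity with
    type-II likelihood-ratio tests and effect sizes, and a forward simulator
    of sl-CSD populations for generating synthetic datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
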