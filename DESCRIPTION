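Package: sexsys
Title: Sex Chromosome System Inference from RNA-Seq SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the sex-determination system of a species (no sex
    chromosomes, male heterogamety XY, or female heterogamety ZW) from
    biallelic SNP genotypes called on RNA-seq data of sexed individuals.
    Per-gene mixture likelihoods contrast Hardy-Weinberg genotype
    frequencies with the gametolog equilibrium expected for sex-linked
    genes; models are compared by BIC, sex-linked genes are called by
    posterior probability, fixed heterogametic SNP patterns are flagged,
    and robustness is assessed by exhaustive sex-label permutation.
    Includes a seeded genotype simulator with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
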