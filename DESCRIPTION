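Package: matescan
Title: Genome-Wide Spousal Genetic Similarity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistics for detecting genetic assortative and disassortative
    mating from couple-paired SNP genotypes. Implements the identity-in-state
    relatedness coefficient R1 with spouse-reshuffling permutation tests, the
    per-SNP spousal dosage correlation R2 with permutation, analytic and
    genome-background significance, signed Fisher regional meta-analysis with
    recombination-matched genome backgrounds, HLA allele-sharing scores with
    permutation backgrounds and an Anscombe-Glynn kurtosis diagnostic, the
    couple-similarity by population-homozygosity contingency analysis, and a
    Mendelian parent-offspring heterozygosity simulation. Includes a synthetic
    couple-genotype generator with controllable spousal dosage correlation so
    the whole pipeline is testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
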