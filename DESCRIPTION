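Package: geneburden
Title: Gene-Centric Inherited Disease Burden from Ancestry-Stratified Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the population burden of Mendelian disease from
    ancestry-stratified allele-count summaries of classified variants.
    Computes per-gene cumulative allele frequencies, Hardy-Weinberg carrier
    frequencies and genetic prevalences under autosomal dominant, recessive
    and X-linked inheritance models; aggregates burden across genes, ICD-10
    disease groups and genetic ancestries; derives carrier-screening
    candidate sets and secondary-findings reports; and converts prevalences
    to absolute affected counts. Includes a synthetic-data generator with
    known ground truth and a genotype-level simulator that serves as a
    brute-force check of the analytic formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
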