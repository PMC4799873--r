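Package: founderage
Title: Founder-Effect Haplotype Analysis and Allele-Age Estimation for
    X-Linked Disease Mutations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of recurrent disease mutations on hemizygous X
    chromosomes genotyped at flanking microsatellite (STR) markers:
    inference of the ancestral (founder) haplotype and haplotype grouping,
    allelic association between mutation and marker alleles (difference in
    proportions with Wald intervals, Fisher's exact test, and the
    Bengtsson-Thomson linkage-disequilibrium delta), two-point LOD-score
    linkage analysis, and moment-based allele-age estimation with the
    Luria-Delbrueck growth correction and demographic calibration of the
    population growth rate. Includes a forward-time branching-process
    simulator of founder-haplotype decay for parameter-recovery validation
    and a rejection-ABC posterior for the mutation age.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
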