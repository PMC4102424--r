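Package: imsat
Title: Detection and Population Analysis of Interrupted Microsatellites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding perfect and interrupted microsatellites (iMSs)
    in DNA sequence by seed detection and iterative extension, quantifying how
    interruptions reduce microsatellite mutability between genomes (mean
    squared repeat-number difference with bootstrap confidence bands), calling
    interruption polymorphisms from population variant sets with
    death/degeneration classification and population-sharing partitions,
    computing the associated population-genetic statistics (heterozygosity,
    F_ST, bootstrap Kolmogorov-Smirnov comparison of heterozygosity
    distributions, haplotype r2 linkage disequilibrium), and deriving DNA
    polymerase error frequencies and mutational spectra from reporter-assay
    mutant data. A synthetic-data module generates every pipeline input with
    full ground truth so all stages run and are testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
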