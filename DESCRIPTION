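Package: steppeadmix
Title: F-Statistics, qpAdm-Style Mixture Models and Admixture Dating for
    Ancient DNA Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for ancient-DNA population genetics built
    around allele-frequency f-statistics. Reads and writes ASCII
    EIGENSTRAT genotype data, produces pseudo-haploid calls from read
    counts, computes f2/f3/f4 and D statistics with weighted block
    jackknife standard errors, runs qpWave-style rank tests and
    qpAdm-style mixture-proportion estimation against an outgroup set,
    fits admixture graphs to observed f-statistics by multi-start least
    squares with a consecutive-grafting topology search, dates admixture
    pulses from the exponential decay of weighted linkage disequilibrium,
    and assigns genetic sex and pairwise kinship for sample QC. A
    synthetic-data module simulates allele frequencies drifting along an
    admixture graph (Balding-Nichols model), pseudo-haploid genotypes,
    mosaic admixed haplotypes and sex-chromosome read counts, so that
    every inference stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
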