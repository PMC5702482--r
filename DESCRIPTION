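Package: assortmate
Title: Ancestry-Based Assortative Mating from Genome-Wide SNP Genotypes
Version: 0.1.0
Authors@R:
    person("assortmate", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies ancestry-based assortative mating (endogamy) in
    family studies from genome-wide SNP genotypes. Implements SNP quality
    control (call-rate and minor-allele-frequency filters, windowed LD
    pruning), genome-wide principal component analysis with Patterson
    normalization, spouse-pair identification from pedigrees via in-common
    children, per-component spouse correlations with Fisher-z confidence
    intervals, and a random within-ethnicity pairing null distribution.
    Includes a forward simulator of two-generation multi-subpopulation
    cohorts under the Balding-Nichols model with a tunable endogamy rate,
    so the whole pipeline can be exercised without controlled-access data.
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
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
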