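Package: saltadapt
Title: Quantitative Analysis of Mutator-Driven Adaptation in Yeast Serial-Transfer Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of microbial experimental-evolution
    studies in which a mismatch-repair (MMR) defect elevates the mutation supply.
    Implements serial-transfer generation accounting and relative fitness from
    marked competition assays, Luria-Delbruck fluctuation-assay mutation-rate
    estimation (Lea-Coulson method of the median with Dixon-Massey nonparametric
    confidence intervals), bulk-segregant pool-sequencing linkage via two-sided
    Fisher exact tests, cataloguing and codon-level annotation of adaptive
    mutations from clone sequencing tables, tetrad segregation and dominance
    classification, and a genotype-class Wright-Fisher style serial-transfer
    simulator in which mutation supply (rate times bottleneck size) governs the
    timing of adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
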