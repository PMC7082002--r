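Package: sangerhet
Title: Heteroplasmy Detection and Inheritance Analysis from Sanger Trace Peaks
Version: 0.1.0
Authors@R:
    person("Elba", "Couto", email = "ecouto@example.org", role = c("aut", "cre"))
Description: Quantifies mitochondrial heteroplasmy from paired-read Sanger
    electropherogram peak heights, calls heteroplasmic sites with replicate
    confirmation, enumerates haplotypes and single-molecule (clone) site
    combinations, discriminates competing explanations for double peaks
    (nuclear mitochondrial pseudogenes, mitochondrial gene duplication,
    doubly uniparental inheritance, de novo mutation, paternal leakage)
    by explicit elimination rules over pedigree, tissue-panel and clone
    evidence, and models mother-to-egg transmission through a binomial
    germline bottleneck with a moment estimator of the effective
    bottleneck size. Ships a labelled trace simulator so every stage is
    testable against generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
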