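Package: divrate
Title: Predicting Intraspecific Genetic Diversity from Long-Term
    Molecular Evolutionary Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the long-term molecular evolutionary rate of
    a gene, summarized from the branch lengths of its phylogenetic gene tree,
    to its intraspecific genetic diversity. Implements closed-form estimation
    of multiplicative gene and branch effects for branch-length matrices, a
    background-selection model of 1000-bp window nucleotide diversity with
    rate-dependent selective effects on exons, bias-corrected (disattenuated)
    correlations between rates and diversity, negative-binomial regression
    baselines for segregating-site counts, and a gene-set deviation test that
    detects lineage-specific enhanced or reduced functional constraints.
    Includes seeded synthetic-data generators emulating each model so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    MASS,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
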