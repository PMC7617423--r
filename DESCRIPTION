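Package: coalbin
Title: Coalescent Theory of Taxonomic Binning Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for the accuracy of taxonomic
    binning of sequencing reads under a two-reference-species coalescent
    model. Computes the probabilities that a query read is assigned to the
    correct reference, to the wrong reference, or left unassigned under the
    least-mismatch and exact-match rules, by numerical integration of
    case-wise coalescent genealogy integrals with Poisson mutation counts.
    Extensions cover sample ages, query-reference divergence, incomplete
    reference sequences (breadth of coverage) and time rescaling for large
    population sizes. Includes a Monte Carlo genealogy oracle, a
    sequence-level read simulator with an ancient-DNA deamination model and
    FASTA output, parameter sweeps, and an Ursid ancient environmental DNA
    scenario preset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
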