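Package: barcodegap
Title: Barcode-Gap Species Delimitation with Integrative Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based species delimitation for DNA-barcode data and its
    refinement against morphology and nuclear evidence. Collapses aligned
    mitochondrial sequences to haplotypes, computes Kimura two-parameter
    distances with pairwise deletion, partitions haplotypes at automatically
    detected barcode gaps over a sweep of prior intraspecific divergences,
    and selects a primary species hypothesis by a stability rule. Putative
    species are then refined to a secondary species hypothesis by
    integrating neighbour-joining bootstrap monophyly with morphological
    distinctness (split/merge rules), compared against a known faunal
    checklist, and screened for mitochondrial/morphological conflicts
    diagnostic of one-way introgression. A calibrated two-parameter
    sequence simulator with planted species structure, haplotype sharing,
    unbalanced sampling and introgression provides ground-truth datasets
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
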