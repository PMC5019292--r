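Package: karyobarcode
Title: Karyotype Characterization and COI Barcode Divergence for Loaches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two classic desk analyses of a fish
    cytogenetics-and-barcoding study. The cytogenetic track turns
    per-chromosome arm measurements into arm ratios, centromeric indices,
    Levan morphology classes, karyotype formulas, fundamental numbers and
    haploid idiograms (SVG or base graphics). The molecular track computes
    pairwise nucleotide distances (p, Kimura two-parameter, Tamura-Nei,
    with optional discrete-gamma rate correction), between-species mean
    divergences, neighbor-joining trees with nonparametric bootstrap
    supports, and outgroup-rooted species-monophyly tests. A simulation
    module generates measurement tables and gamma-heterogeneous alignments
    with known ground truth, and bundled fixtures reproduce a published
    three-species loach karyotype table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
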