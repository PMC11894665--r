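Package: sulfoscan
Title: Detecting Sulfotyrosine Misidentified as Phosphotyrosine in
    Phosphoproteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tyrosine sulfation (+79.956815 Da) and tyrosine phosphorylation
    (+79.966331 Da) are near-isobaric, so sulfopeptides in phosphoproteomics
    builds are routinely reported as phosphopeptides. sulfoscan recalibrates
    peptide-spectrum-match precursor mass errors per MS run, aggregates them
    by nonstrict peptidoform, fits 1-3 component univariate Gaussian mixtures
    with BIC model selection, and assigns peptidoforms to predefined
    mass-error bins to shortlist sulfation candidates. Downstream stages
    automate histogram calling (s/ss/p types), over-representation analysis
    against GO-style and sulfation-context term maps, flanking-residue acidity
    composition, and dual-hypothesis MS2 fragment annotation with full
    neutral loss of the sulfate group (ProForma curly-brace notation,
    Universal Spectrum Identifiers). A seeded synthetic-build generator
    supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
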