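Package: pepfreq
Title: Spectral-Counting Differential Analysis of Endogenous Plasma Peptidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential analysis of endogenous tryptic peptides and
    phosphopeptides observed by LC-ESI-MS/MS across disease and control
    plasma treatments. Implements the full spectral-counting workflow:
    ingestion and validation of peptide-spectrum-match (PSM) tables,
    precursor-intensity filtering, best-fit deduplication of redundant
    charge-state correlations, independent tryptic (TRYP) and
    phospho-tryptic (STYP) analysis streams, observation-frequency
    counting per gene symbol with total-count depth correction, a
    pseudocounted one-cell chi-square statistic with nominal df=1
    p-values and Benjamini-Hochberg FDR control, candidate selection,
    log10 precursor-intensity means and one-way/two-way ANOVA across
    treatment panels, in-silico tryptic digestion and hydropathy
    utilities, protein-interaction network descriptors, and a
    ground-truth synthetic PSM generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    igraph,
    Biostrings,
    car,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
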