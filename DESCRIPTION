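Package: plasmaquant
Title: Label-Free Quantification and Differential Abundance for Plasma
    LC-MS/MS Peptide Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for label-free quantification of plasma
    proteomics data from per-sample peptide-level search-engine exports.
    Retention times are calibrated across runs against a reference sample by
    robust LOWESS regression, peptide features are grouped into cross-run
    clusters by mode seeking within ppm mass and relative retention-time
    windows, clusters are annotated with a representative sequence and a
    single protein by frequency rules, and peak areas are imputed,
    ppm-normalized and summed to protein abundances. Differential abundance
    between cases and controls is assessed by Mann-Whitney tests with
    fold-change and peptide-count criteria in a discovery set and verified by
    expression trend and fold change in an independent test set. A synthetic
    multi-run study generator with known ground truth (retention-time drift,
    ppm mass error, missingness, spiked group effects) supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
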