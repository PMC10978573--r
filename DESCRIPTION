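Package: nanomlm
Title: Masked Language Modelling Workbench for Nanobody Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Desk-scale toolkit for residue-level masked language models of
    immunoglobulin heavy-chain variable domains. Provides a synthetic
    repertoire simulator (germline scaffolds, somatic hypermutation, CDR3
    resampling, sequence-dependent property labels), IMGT numbering by
    scaffold alignment with region segmentation and hallmark-motif
    extraction, a from-scratch bidirectional transformer encoder trained
    with the masked-language-model objective, a positional infilling
    benchmark aggregated by IMGT region against a position-specific scoring
    matrix baseline, a sequence nativeness statistic, four-layer dense
    fine-tuning heads for species classification and thermostability
    regression with identity-filtered 8:1:1 splits, and germline
    edit-distance diagnostics for gene-assignment quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
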