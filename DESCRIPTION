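Package: poltraffic
Title: Quantitative Models of RNA Polymerase II Traffic Under Methyl-CpG Protein Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative in-silico ChIP-seq and ATAC-seq models with
    footprint and occupancy fitting, open-boundary TASEP (totally
    asymmetric simple exclusion process) engines for transcription
    elongation with static slow sites or dynamically binding obstacles,
    mechanistic gene-expression models (chromatin condensation,
    polymerase detachment, elongation congestion), and a
    fit-on-one-line/predict-the-rest discrimination protocol that ranks
    the mechanisms against methylation-density-binned differential
    expression. Includes synthetic genome, methylome and cell-line panel
    generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
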