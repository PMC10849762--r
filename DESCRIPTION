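Package: invadeR
Title: Multiomic Quantification of Glioblastoma Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying metabolic drivers of glioblastoma
    invasion from multiomic experiments. Scores pooled CRISPR knockout
    screens from guide-level sgRNA counts to gene-level
    invasion-essentiality calls (counts-per-million normalization,
    nontargeting-referenced log2 guide fitness, median gene scores,
    one-sample deviation tests); quantifies invasion phenotypes from
    calibrated microscopy masks (invasion index, detached-cell and
    highly-invasive-cell rules, elongation classes); estimates
    box-counting fractal dimensions of tumor boundaries as an in vivo
    invasiveness score; and performs paired core-versus-invasive
    differential abundance, concordance, and hypergeometric
    over-representation analysis for metabolite, lipid, and gene
    matrices. Seeded synthetic-data generators emulate each input so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    tiff,
    optparse
Config/testthat/edition: 3
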