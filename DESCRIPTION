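Package: ckpipe
Title: Meta-Analysis of Cytokinin Transcriptomics and Promoter
    Cis-Element Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for cytokinin transcriptomics
    meta-analysis in Arabidopsis thaliana and rice: averaging of
    treated-versus-control expression ratios across experiments and time
    points, k-of-n core-set extraction across independent regulated-gene
    lists, differential-expression calling with Benjamini-Hochberg FDR
    control, an iterative reciprocal-top-hit orthology rule over tabular
    similarity hits, and an exhaustive degenerate-octamer promoter
    enrichment screen that proposes candidate cytokinin response cis
    elements, with position-frequency-matrix sequence logos. Includes
    seeded synthetic-data generators for every input so the whole chain
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
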