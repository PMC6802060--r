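Package: retrotracer
Title: Retrocopy Discovery, Dating and Chromosomal Gene-Traffic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects RNA-based gene duplicates (retrocopies) in an annotated
    genome by six-frame seeded protein-to-genome search and a splice- and
    frameshift-aware alignment, classifies them as intact retrogenes or
    retropseudogenes, flags chimeric insertions into host genes, estimates
    selection pressure with the Nei-Gojobori (NG86) Ka/Ks counting method,
    dates insertions from synonymous divergence (T = Ks / 2 lambda), scores
    transcription support from EST reads, and tests for biased gene traffic
    on and off the X chromosome. Includes a synthetic-genome simulator with a
    ground-truth event table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
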