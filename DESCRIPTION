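Package: relscan
Title: Bernoulli Spatial Scan Statistics and Relative Scan Statistics for
    Genomic Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cluster detection in binary genomic event data (for example
    viral vector integration sites) with the Bernoulli-model spatial scan
    statistic, and localization of genomic regions where two event series
    show unshared rate variation with a bivariate relative scan statistic.
    Candidate zones are event-delimited genomic intervals; mappability
    ("blind region") masks are subtracted strand-aware from the Bernoulli
    trial set; inference uses Wilks likelihood-ratio tests with
    Holm-Bonferroni family-wise error control and a sequential
    secondary-cluster detection loop. Includes a synthetic-data generator
    for null, shared-rate-variation and planted-cluster scenarios, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
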