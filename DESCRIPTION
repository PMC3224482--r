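Package: stressrcr
Title: Reverse Causal Reasoning on Signed Causal Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for upstream-regulator inference on signed causal biological
    networks. Represents evidence-annotated causal knowledge graphs of the kind
    used to model cellular stress signalling, calls directional gene expression
    "state changes" from two-group microarray comparisons (quantile
    normalization, pooled-variance tests, Benjamini-Hochberg adjustment, fold
    change and significance filters), and scores every eligible network node as
    a candidate upstream cause of the observed changes using hypergeometric
    richness and binomial concordance statistics (reverse causal reasoning).
    Includes coverage and prediction-pattern analytics and a synthetic
    experiment generator with planted active regulators for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    xml2
Config/testthat/edition: 3
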