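Package: conet
Title: Co-Occurrence Networks from Term-Annotated Document Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds concept co-occurrence networks from term-annotated
    document collections (MEDLINE-style citation XML or plain doc-term
    tables), reduces them with a chi-square test of independence with
    Yates continuity correction, and characterises their macroscopic
    topology: small-world metrics against Erdos-Renyi baselines,
    discrete power-law degree-distribution fitting by maximum likelihood
    with Kolmogorov-Smirnov lower-bound selection and bootstrap
    goodness-of-fit, effective diameter, degree assortativity,
    clustering-by-degree hierarchy, and robustness under targeted and
    random node-removal attacks. Includes a synthetic corpus generator
    with planted term associations so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
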