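Package: tbiconn
Title: Structural Connectome Analysis of Traumatic Brain Injury Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted structural brain networks from streamline-count
    connectivity matrices, computes weighted graph-theory measures (strength,
    global and local efficiency, clustering coefficient, characteristic path
    length, betweenness centrality), identifies network hubs by ranked
    betweenness centrality, and runs the dose-response group statistics
    (one-way ANOVA, LSD post-hoc tests, Benjamini-Hochberg false discovery
    rate control) and Pearson correlations between network measures and
    cognitive change scores. Includes a synthetic connectome cohort generator
    emulating severity-graded edge attenuation across control, mild and
    moderate-severe traumatic brain injury groups, so the full pipeline can
    be exercised and validated without access to confidential subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
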