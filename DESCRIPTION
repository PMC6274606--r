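Package: crossaggr
Title: Cross-Species Integration of Aggression Gene Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates gene-level evidence for aggressive behaviour across
    human and rodent studies. Provides gene-list ingestion with ortholog
    mapping, pairwise gene-set overlap testing by one-tailed Fisher's exact
    test over a fixed gene universe, evidence-weighted gene ranking, a
    simplified weighted co-expression module stage with eigengene-trait
    association and Benjamini-Hochberg correction, hypergeometric pathway
    enrichment against GMT collections with binary profile coding, classical
    metric multidimensional scaling on Rogers-Tanimoto dissimilarities, and
    interaction-network degree comparison of evidence classes via median
    regression with bootstrap inference. A seeded synthetic-data generator
    produces inputs with the statistical structure each stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
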