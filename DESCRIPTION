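Package: icefacets
Title: Tiered Ecosystem Classification of Ice-Free Landscapes from
    Latent Environmental Facets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for hierarchical classification of
    ice-free landscapes on a regular grid. Tier 1 partitions abiotic
    variation into Major Environmental Units by factor analysis with
    deterministic maximum-score classification; Tier 2 subdivides each
    unit into Habitat Complexes from double-log-transformed habitat
    suitability surfaces, with nibble gap filling; distinct overlay
    ecosystems (geothermal areas, seabird colonies, lakes) are mapped by
    rule-based workflows and stacked with fixed precedence; Tier 3
    intersects the result with bioregions and amalgamates marginal
    fragments into Bioregional Ecosystem Types. Includes factor-count
    selection by parallel analysis, a per-pixel dominance confidence
    index, plain-text raster/vector I/O, and a seeded synthetic
    landscape generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
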