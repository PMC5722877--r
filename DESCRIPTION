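Package: drydisp
Title: Community Dispersion Analysis of Drought-Response Gene Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links inter-specific similarity in transcriptomic response to
    experimental drought with the spatial co-occurrence of tree species in a
    mapped forest plot. Provides per-species gene set enrichment (Fisher exact
    tests with Benjamini-Yekutieli correction over a shared GO universe),
    conversion of enrichment profiles, functional traits, phylogenies and
    tolerance scores into species dissimilarity matrices, abundance-weighted
    mean pairwise distance with taxa-label null models and standardized effect
    sizes per subplot, ordinary kriging of soil moisture from a nested core
    design, torus-translation correlation tests, phylogenetic signal statistics
    (Mantel, Fritz-Purvis D for binary enrichment states), and a synthetic-data
    generator with known guild structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
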