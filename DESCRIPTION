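Package: diseasome
Title: Cross-Comparison of Gene Age, Regulation, Tissue Specificity and
    Disease Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: All-against-all cross-comparison of binary gene attributes in
    hereditary-disease gene sets. Derives the standard dichotomies (old/new
    by phylostratum of origin, tissue-specific/housekeeping by expression
    breadth, regulator status from transcription-factor and
    post-translational-modification annotation, sequence length, disease and
    interaction status), cross-tabulates them into a contingency matrix with
    unpooled two-proportion z-tests, fold changes and odds ratios, computes
    Pearson and partial correlations conditioned on tissue specificity,
    analyses interaction-network connectivity via least-squares means and
    age-assortative mixing with permutation tests, profiles attributes
    across phylostrata, tissues and chromosomes with confidence bands and
    two-way hierarchical clustering, and ships a seeded synthetic-data
    generator emulating the statistical structure of the merged human gene
    dataset such analyses are run on, together with the published summary
    contingency table as an embedded fixture.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    pracma,
    withr
Config/testthat/edition: 3
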