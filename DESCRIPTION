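Package: pairdrs
Title: Target-Aware Drug-Drug Relationship Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a drug-drug relationship score (DRS) that ranks drug pairs
    by how likely they are to share a protein target. Drugs are represented by
    principal components of their molecular descriptors; each unordered pair is
    encoded as the per-component mean (M) and squared difference (E) of the two
    projections; an ensemble of Random Forests, each trained against a
    different inverse-density under-sampled set of non-target-sharing pairs,
    votes on target sharing, and the averaged vote rescaled to [-1, 1] is the
    DRS. Includes target prediction by maximum-score annotation transfer,
    evaluation utilities (sensitivity/specificity sweeps, Tanimoto fingerprint
    baselines, protein-domain matching ratios, ATC-code matching curves), and a
    synthetic bipartite drug-target data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineR
Config/testthat/edition: 3
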