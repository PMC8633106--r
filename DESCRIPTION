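Package: netpharm
Title: Network Pharmacology Screening of Herbal Formula Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computational network-pharmacology toolkit for multi-component
    herbal formulas. Screens formula components with ADME rule sets (Lipinski
    rules, oral bioavailability, GI absorption, hERG inhibition,
    carcinogenicity), assembles component-target-pathogenic-gene-disease
    networks on top of protein-protein interaction data, ranks nodes with a
    diameter-normalised transit-path importance score to extract the effective
    intervention space, selects the core group of functional components by a
    cumulative-coverage greedy procedure or a 0/1 knapsack, scores
    receptor-to-effector signalling cascades with a maximum-targeting-weight
    model, and evaluates gene lists by hypergeometric over-representation
    against GMT collections. Includes a seeded synthetic-data generator that
    emulates every input layer so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
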