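Package: causenet
Title: Literature-Mined Causal Disease Networks for Clinical Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines directed disease-disease causal assertions from sentence
    corpora with dictionary matching and lexical patterns, scores each relation
    with five evidence measures computed from patient first-diagnosis records
    and background-knowledge judges (phi coefficient, chi-square dependence
    with Benjamini-Hochberg control, temporal diagnosis-date correspondence,
    annotation support, and a yes/no language-model judge), assembles the
    scored relations into a directed acyclic graph by greedy score-descending
    insertion with cycle removal, and applies the graph to backdoor-adjusted
    interventional queries, multi-parent modified polygenic risk scores, and
    conditional-independence dissection of variant pleiotropy. Includes a
    fully seeded synthetic-data generator producing every pipeline input from
    a known ground-truth world.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
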