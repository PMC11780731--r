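Package: walklrp
Title: Walk-Based Relevance Explanations for Message-Passing Interatomic
    Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Explains what an invariant message-passing interatomic
    potential has learned by decomposing its predicted energy onto walks
    over the molecular graph with layer-wise relevance propagation
    (GNN-LRP), and summarising the resulting walk distribution with
    interaction metrics: walk importance and extent, interaction range
    (threshold and generalized-expectation statistics), inclusive and
    exclusive pairwise interaction strength, element-pair strength
    matrices, many-bodyness profiles, and exponential versus power-law
    decay fits. Ships a small trainable continuous-filter convolution
    potential, synthetic conformer generators with analytic Morse and
    three-body labels that provide ground truth for every metric, and an
    experiment driver that tracks the interaction range over training and
    classifies molecular-dynamics energy series for stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
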