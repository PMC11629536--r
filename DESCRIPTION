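Package: molhitl
Title: Human-in-the-Loop Active Learning for Goal-Oriented Molecule Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Couples a goal-oriented molecule generator with an active-learning
    loop that refines a random-forest property predictor from (simulated or
    real) expert feedback. Provides a self-contained SMILES toolkit (parsing,
    canonicalization, Morgan count fingerprints, Murcko-type scaffolds,
    Tanimoto similarity), weighted multi-component scoring with [0,1]
    transforms, a tree-ensemble predictor with per-tree access and
    confidence-weighted fine-tuning, four data-acquisition criteria (expected
    predictive information gain, ensemble uncertainty, greedy, random) over a
    score-weighted target distribution, simulated noisy experts, a
    diversity-filter scaffold memory, and an orchestrated generation /
    feedback loop with distribution-learning evaluation metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
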