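Package: comorbnet
Title: Temporal Bipartite Networks for Multimorbidity Trajectories in
    Severe Mental Illness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds temporal bipartite patient-diagnosis networks from
    hospital admission episodes of patients with severe mental illness
    (schizophrenia, F20, or bipolar disorder, F31), quantifies
    multimorbidity change around the index diagnosis (new versus
    re-occurring conditions, new-conditions-per-year, chapter-level
    lift), tests structural properties (degree mixing, second-order
    neighbourhoods, peer-attribute correlation, average efficiency)
    against degree-preserving null models, and classifies the drivers of
    network clustering with temporal bipartite graphlets. A
    seed-reproducible synthetic cohort generator with switchable
    selection, progression and recurrence mechanisms replaces
    non-deposited clinical data so the whole pipeline is exercisable and
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
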