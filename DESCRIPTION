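Package: vtplanner
Title: Virtual Treatment Planner for Automatic Radiotherapy Inverse Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale intelligent automatic treatment planning framework
    for head-and-neck radiotherapy. A hierarchical deep-Q-learning agent (the
    virtual treatment planner) operates an inverse fluence-map optimizer by
    iteratively adjusting objective priorities to maximize a 21-metric,
    150-point plan-quality score. Includes a synthetic voxel phantom
    generator with the structure algebra used to derive auxiliary planning
    structures, a linear beamlet dose engine, a dose-volume-objective
    optimizer, DVH-based plan scoring, epsilon-greedy Q-learning with
    experience replay, a closed-loop autoplanning workflow, and paired
    non-inferiority plan comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
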