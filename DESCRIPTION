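Package: cogrank
Title: Personalized Ranking of Cognitive Biomarkers from Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits joint push and learning-to-rank latent factor models
    (PLTR and its hinge-margin variant PLTR_h) that prioritize cognitive
    assessment features for individual patients using patient similarity
    derived from structural MRI morphometry. Includes the accompanying
    preprocessing pipeline (group-difference screening, min-max scaling with
    effect-size orientation, degeneracy filtering, RBF patient similarity),
    feature- and task-level ranking metrics (QH@k, WQH@k, NH_g@k),
    task-wise cross-validation and leave-out validation protocols with
    cold-start latent inference, grid search, and a synthetic cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
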