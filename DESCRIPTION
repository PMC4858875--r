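Package: hoseNMR
Title: Self-Learning Proton Chemical Shift Prediction and Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-training system for 1H NMR analysis that couples a
    HOSE-code (Hierarchically Ordered Spherical description of Environment)
    nearest-fragment chemical shift predictor with an integral- and
    shift-constrained combinatorial assigner. Starting from unassigned
    peak lists, consensus assignments (nucleus-shift dyads common to every
    feasible solution of a molecule) seed a fragment-shift database that
    in turn constrains later assignment rounds, so prediction accuracy and
    assignment power bootstrap each other without any human-assigned
    training data. Includes an MDL molfile (V2000) reader with explicit
    hydrogen completion, graph-symmetry proton equivalence classes, a
    deterministic HOSE-style fragment encoder, a branch-and-bound
    assignment enumerator, the batch self-learning loop with evaluation
    metrics, and a synthetic corpus generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), ChemmineR, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
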