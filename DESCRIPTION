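Package: gridnav
Title: Model-Based Analysis of Goal-Directed Navigation in Grid Worlds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing goal-sequence navigation behaviour on occupancy
    grids. Implements visibility-based, goal-directed, mixture and
    sequencing-error navigation policies over an 8-connected grid Markov
    decision process, maximum-likelihood fitting of the softmax inverse
    temperature and of the mixture weight (goal-directedness), trajectory
    preprocessing (orientation reduction, interpolation, goal segmentation),
    map and behavioural metrics (goal exposedness, online disclosure,
    tortuosity, normalized time, speed, angular velocity), robust and
    bootstrap statistics (biweight midcorrelation, R-squared gain test), and a
    synthetic age-structured cohort generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
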