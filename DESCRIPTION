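Package: oepcr
Title: Detection of Object Exploration-Dependent Place Cells on Annular Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium-imaging recordings of
    hippocampal CA1 made while mice run laps on an annular track with objects
    placed at fixed angular positions. Converts trajectories to maze-centered
    polar coordinates, segments laps and object-pass bouts, computes spatial
    information (Skaggs mutual information in bits) with a circular-shift
    shuffle null, classifies place cells, and identifies object
    exploration-dependent place cells (oePCs) via a bout-label bootstrap test
    with a Difference Index. Includes reward-associated cell detection,
    speed-drop event analysis, linear-SVM leave-one-out decoding of
    exploration versus non-exploration behavior, off-track and head-direction
    outlier exclusion, and a fully seeded synthetic session generator with
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, e1071, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
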