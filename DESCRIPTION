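Package: gazecross
Title: Gaze Behaviour and Crossing Decisions in Dynamic Road-Crossing Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for eye-tracking studies of road-crossing
    behaviour. Parses 1000 Hz gaze sample streams into fixations, saccades
    and smooth pursuits (velocity threshold plus polynomial-dispersion
    pursuit scoring), builds smoothed z-scored gaze maps and Fisher-z gaze
    similarity matrices with participant-level bootstrap confidence
    intervals, performs pixel-wise statistical mapping with bootstrap
    cluster correction, provides robust decision statistics (k-means++
    clustering, Yuen's trimmed-mean test, Harrell-Davis shift functions,
    traffic-density dichotomisation), estimates traffic density from video
    frames by Gaussian-mixture background subtraction and blob analysis,
    and generates fully synthetic cohorts (labelled scanpaths, decision
    records, toy traffic videos) with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
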