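Package: scanpathr
Title: Gaze-Pattern Analysis of Perception and Visual Mental Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of fixation sequences recorded during scene perception and
    visual mental imagery. Implements recurrence quantification analysis of
    scanpaths (recurrence rate, determinism, laminarity, fixation spread),
    MultiMatch-style five-dimension scanpath similarity (shape, length,
    direction, position, duration), quadrant area-of-interest profiles and the
    looking-at-nothing association between encoding and imagery, velocity and
    acceleration based fixation detection from raw gaze samples, fixation-report
    filtering with quality summaries, participant-level cluster-bootstrap
    condition contrasts, and a seeded synthetic scanpath generator emulating
    free viewing, part-based viewing (gaze-contingent window), holistic viewing
    (artificial scotoma), and imagery-like gaze so the whole pipeline is
    testable without any recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
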