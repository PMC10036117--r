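Package: ymazenav
Title: Y-Maze Spatial Navigation, Gaze Dwell and Strategy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for immersive Y-maze spatial navigation
    experiments with head tracking and binocular eye tracking. Provides a
    parametric geometric model of landmark-polarized and geometry-polarized
    Y-mazes with gaze ray casting against walls, floor and sky; a seeded
    agent-based simulator emitting head-pose (30 Hz) and gaze (120 Hz)
    streams with known ground-truth strategies; trial segmentation and the
    standard navigation measures (escape latency, traveled distance,
    orientation and navigation durations, speed, time in the central area);
    egocentric versus allocentric strategy classification from probe trials;
    gaze-to-surface dwell-time proportions, landmark-sector analysis, binned
    time courses and heatmaps; and the statistical layer (logistic
    age-by-condition models with probability-scale second differences,
    Fisher exact tests with odds ratios and effect sizes, rank tests with
    r = z/sqrt(N), chi-square power analysis, and a gaze-altitude strategy
    classifier validated by repeated 25 percent hold-out and leave-one-out).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow
Config/testthat/edition: 3
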