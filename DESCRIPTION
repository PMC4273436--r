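Package: flyvalence
Title: Behavioral Valence Analysis for Fly Quadrant Arenas, Conditioning
    Assays and Activity Monitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying behavioral valence in Drosophila group
    assays. Computes quadrant preference time series and light preference
    indices from tracked trajectories in four-quadrant optogenetic arenas,
    segments and classifies choice-zone visits at the light on/off border
    (entry-angle and prior-movement filters, crossing versus turn-around
    outcomes, choice probability), and derives locomotor kinematics (walking
    speed, angular speed) conditioned on illumination state. Scores
    reciprocal-design memory tests (T-maze olfactory, visual arena, Y-maze)
    as performance indices, and scores sleep from Drosophila Activity
    Monitor beam-crossing counts (5-min inactivity bouts, daily sleep,
    percent sleep change across baseline/activation/recovery phases, waking
    activity). Includes the matching statistical procedures (test of equal
    proportions, Dunn-Sidak correction, Kruskal-Wallis with Dunn's
    post-test, rank correlations) and seeded synthetic generators
    (correlated-random-walk arena cohorts with a tunable valence parameter,
    two-state Markov activity records, reciprocal two-choice experiments)
    so every analysis stage can be exercised and calibrated without raw
    video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
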