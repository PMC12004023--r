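Package: navcog
Title: Gamified Spatial-Cognition Task Protocols, Scoring, and
    Measurement-Property Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A headless engine for serious-game spatial-cognition
    assessment: deterministic generators and scorers for a hidden-goal
    navigation task, a mental-rotation task, and a Corsi block-tapping
    span procedure, including a trajectory anomaly detector; the
    measurement-property toolkit used to validate such instruments
    (item content-validity index, chance-corrected modified kappa,
    Aiken's V with score-type confidence intervals, rank-biserial and
    Cramer's V effect sizes, two-round Delphi comparison); scoring for
    a 15-item usability questionnaire and an 8-criterion digital
    ergonomics questionnaire; and a synthetic cohort simulator with
    known ground truth for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
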