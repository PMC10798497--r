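Package: tensiontrend
Title: Trend-Salience Prediction of Continuous Musical Tension from Audio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts continuously rated musical tension from audio. Six
    musical features (loudness, roughness, onset frequency, tempo, pitch
    height, tonal tension) are extracted on a common 10 Hz grid and combined
    under the trend-salience principle: local feature slopes are estimated in
    sliding attentional windows, amplified when the directly preceding memory
    window trends in the same direction, integrated with a decaying moving
    average, and summed with feature weights. Window sizes and weights are
    fitted against mean continuous ratings by a two-step penalized-regression
    procedure with per-piece intercepts, and evaluated with lag-shifted
    Spearman correlation, RMSE, leave-one-piece-out cross-validation and
    ICC(2,k) inter-rater reliability. A synthetic-data module generates
    audio fixtures, feature corpora, model-generated tension and simulated
    multi-rater slider recordings for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
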