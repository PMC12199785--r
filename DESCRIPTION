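Package: wordgaze
Title: Scoring and Longitudinal Analysis of Infant Eye-Tracking Word
    Recognition Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for longitudinal infant word-recognition studies that
    combine a preferential-looking (looking-while-listening) task and a
    pupillometric mismatch task with parent-reported vocabulary (CDI-style)
    checklists. Provides gaze/pupil stream preprocessing (gap interpolation,
    pupil range filtering, moving-median smoothing), area-of-interest scoring
    in visual-angle coordinates, bias-corrected proportion-of-looking scores,
    baseline-corrected pupil congruency difference scores, pseudorandomized
    trial-sequence generators, a synthetic-cohort simulator with known ground
    truth, expectation-maximization imputation for multivariate missing data,
    Little's MCAR test, Spearman and partial rank correlations, and a
    sensitivity analysis for the minimum detectable correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
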