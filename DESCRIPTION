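Package: gsforce
Title: Force Application Effectiveness Analysis for Giant-Slalom Skiing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse force application effectiveness in giant-slalom
    skiing from dual ski-mounted force plates and a body-worn GNSS trajectory
    unit. Provides a synthetic skier/course simulator with known ground truth,
    multi-rate sensor stream conditioning (calibration, bodyweight
    normalization, cubic-spline resampling, Savitzky-Golay and Butterworth
    filtering, jump-impulse cross-correlation synchronization), turn
    segmentation from trajectory inflections, per-turn kinetic and kinematic
    metrics (arc-fit turn radius, radial force, ratio of force application,
    velocity-normalized mechanical energy dissipation), and a four-level
    stepped statistical model (repeated-measures ANOVA with Holm post-hocs and
    Cohen's d, Pearson correlations with Fisher confidence intervals, and
    stepwise multiple regression with standardized coefficients).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
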