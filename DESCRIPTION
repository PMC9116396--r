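Package: crossforce
Title: Crossover Trial Analysis of Force-Time and Subjective Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-period crossover supplement trials with
    instrumented strength testing. Extracts isometric and isokinetic outcome
    metrics (peak force epochs, rate of force development) from 1-kHz load-cell
    force-time traces using zero-phase low-pass Butterworth filtering and
    relative-threshold onset detection; builds counterbalanced crossover designs
    with coded carryover and period terms; fits random-intercept linear mixed
    models by REML with an optional first-order autoregressive residual
    correlation for repeated visual-analog-scale outcomes, including marginal
    and conditional R-squared; screens residual normality and applies log or
    ordered-quantile normalizing transforms; handles invalid records and missing
    values by predictive-mean-matching multiple imputation with Rubin pooling;
    and provides seeded synthetic-data generators with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
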