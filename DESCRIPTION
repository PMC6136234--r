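Package: glucodyn
Title: Variability and Complexity Analysis of Continuous Glucose Monitoring Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous glucose monitoring (CGM) time
    series across three variability domains: geometric (lagged Poincare plot
    descriptors SD1, SD2, SFE, AFE), information (multiscale sample entropy
    and its complexity index), and fractal scaling (detrended fluctuation
    analysis with short- and long-range exponents), alongside conventional
    glycemic-variability metrics (mean glucose, SD, coefficient of variation,
    time in range). Includes a synthetic CGM generator built on exact
    circulant-embedding fractional Gaussian noise with circadian and meal
    structure, a documented CSV dialect with quality-control screening, and
    cohort-level statistics (ANOVA with Holm-corrected pairwise tests,
    Spearman correlation matrices, standardized multiple regression with
    collinearity and autocorrelation diagnostics, paired comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tibble,
    yaml,
    jsonlite,
    withr,
    car,
    lmtest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
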