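Package: methodcompare
Title: Method Comparison Statistics for Paired Clinical Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable toolkit for method comparison studies in
    clinical and laboratory medicine. Provides Bland-Altman analysis with
    confidence intervals for the bias and the limits of agreement, the
    full McGraw-Wong grid of intraclass correlation coefficients, Lin's
    concordance correlation coefficient, and seven regression estimators
    used in method comparison (ordinary and weighted least squares,
    Deming and iteratively reweighted Deming, Passing-Bablok in exact and
    large-sample subsampling modes, and Theil-Sen), together with the
    assumption checks (normality, difference-versus-mean association,
    Breusch-Pagan heteroscedasticity, Mahalanobis outlier screening) that
    drive an explicit method-selection decision table. The Hadlock I-V
    estimated-fetal-weight formulas are bundled as a worked application,
    with a seeded synthetic-data generator for paired measurements and
    fetal biometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    readxl,
    nortest,
    lmtest,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
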