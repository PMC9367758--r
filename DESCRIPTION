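Package: necessity
Title: Necessary Condition Analysis with Ceiling Lines, Permutation Tests,
    and Bottleneck Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates to what extent an independent variable is a necessary
    (but not sufficient) condition for an outcome. Fits ceiling lines on
    bivariate scatterplots by ceiling envelopment with a free disposal hull
    (CE-FDH, a non-decreasing step function) and by ceiling regression
    (CR-FDH, a straight line through the step's corner points), computes the
    necessity effect size d (ceiling zone over empirical scope), its
    approximate permutation significance test, ceiling accuracy, outcome and
    condition inefficiencies, and bottleneck tables giving the minimum
    condition level required for each outcome level. Includes the standard
    preprocessing used in applied necessity studies (mean imputation,
    skewness screening, SD-based outlier removal), benchmark-based
    interpretation of Pearson correlations as a complement, and synthetic
    data generators for ceiling-constrained, independence-null, and
    survey-like datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
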