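Package: aucexcess
Title: Detecting Threshold Excesses in Published AUC Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how discrimination statistics (AUC, AUROC,
    c-statistic) are reported in biomedical abstracts. Parses MEDLINE-style
    abstract XML, extracts AUC values from free text with guards against
    pharmacokinetic areas under the curve and neighbouring statistics,
    summarises the values in a 0.01-wide half-open-bin histogram, fits a
    smooth Poisson natural-spline null to the histogram, and quantifies
    excesses of values just above the salient thresholds 0.7, 0.8 and 0.9.
    Includes a synthetic abstract-corpus generator with a configurable
    threshold "promotion" mechanism and ground truth, plus validation
    statistics (exact binomial confidence intervals, Bland-Altman limits
    of agreement) for comparing algorithmic extraction against manual
    annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    splines,
    stats,
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
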