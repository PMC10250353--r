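Package: acscreen
Title: Activity-Corrected Analysis of Pooled CRISPR Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled CRISPR knockout screens that corrects gene
    fitness estimates for guide RNA cutting activity. Per-guide cutting
    scores derived from a repair-deficient screening arm (or from an
    external activity predictor) are used to remove inactive guides at a
    threshold chosen by maximising the product of the threshold and the
    remaining library coverage. Gene-level fitness scores are tested
    against a Gaussian null estimated by pseudogene resampling from
    putatively non-essential genes, with one- or two-tailed z-tests and
    false discovery rate control. Includes count normalisation and
    abundance QC, a tolerance-screen mode for stress conditions,
    consensus-set evaluation utilities, and a screen simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
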