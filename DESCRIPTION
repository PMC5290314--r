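Package: arpan
Title: Affinity Regression Analysis of Proteogenomic Tumour Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains bilinear ridge ("affinity regression") models that link
    upstream (phospho)protein signalling measured by reverse-phase protein
    arrays to downstream transcriptional programs through a binary
    transcription-factor motif-hit matrix. From a trained interaction matrix
    the package infers per-sample transcription-factor and (phospho)protein
    activities, calibrates their significance against permutation-based
    empirical nulls with Benjamini-Yekutieli false-discovery control,
    associates binary somatic alterations (singly and in pairs) with activity
    changes via ridge regression and permutation-tested coefficients, and
    screens inferred activities against survival with Cox models, risk
    stratification and concordance validation. A synthetic-cohort generator
    drawn from the same bilinear generative model makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
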