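Package: cowfam
Title: Familial Concordance of Circle of Willis Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of circle of Willis variants from
    vessel diameters, within-family concordance of variants against a
    designated proband, a constrained random-matching resampling design with
    an exact conditional logistic events/trials model (noncentral
    hypergeometric conditional likelihood), inverse-variance fixed-effects
    meta-analysis with Higgins I-squared, and a synthetic family-cohort
    generator with tunable familial aggregation for calibration and power
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), survival, metafor, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
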