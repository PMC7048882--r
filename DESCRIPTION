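Package: tscoremap
Title: T-Score Maps for IRT-Calibrated Patient-Reported Outcome Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds response-interpretation maps for item banks calibrated
    under Samejima's graded response model. For every score on the T metric
    (mean 50, SD 10) the most probable response to each item is identified
    from the item characteristic curves, and contiguous bands over the score
    continuum are assembled into a T-score map. Includes summed-score-to-T
    tables via the Lord-Wingersky recursion, response-pattern EAP scoring,
    inverse fitting of item parameters from printed probability snapshots,
    a predicted-versus-observed validation pipeline (difference scores,
    match rates, Spearman correlations), and a graded-response simulator
    with an exact enumeration oracle for expected match rates.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, minpack.lm
Suggests: testthat (>= 3.0.0), optparse, withr
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
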