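Package: cognorm
Title: Regression-Based Normative Data for a Cognitive Test Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds demographically adjusted normative data for an
    eight-test neuropsychological battery (SDMT, Stroop word/color/
    interference, trail making A/B, letter and category fluency).
    Provides a synthetic cohort generator calibrated to published
    demographic marginals, the cohort screening chain (baseline visit,
    native language, corrected vision/hearing, HADS and MMSE cut-offs),
    Bayesian linear and additive normative models fitted by a blocked
    Gibbs sampler with penalized B-spline smooths of age and education,
    PSIS-LOO model comparison over a drop-one-predictor ladder,
    normative probability mapping of raw scores to z-scores, percentiles
    and qualitative bands, stratified mean/SD table norms, posterior
    effect summaries with highest-density intervals, and a lookup-table
    normative calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
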