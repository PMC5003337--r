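Package: tfspm
Title: Time-Frequency Statistical Parametric Mapping for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-univariate statistical parametric mapping of epoched
    intracranial EEG in the time-frequency plane and in sensor time. Provides
    Morlet wavelet power decomposition with per-frequency log baseline
    correction, trial-level factorial general linear models with restricted
    maximum likelihood (ReML) non-sphericity estimation and whitening,
    random-field-theory cluster-level family-wise-error inference on 1-D and
    2-D statistic images, a label-permutation oracle for validating the
    analytic inference, and a synthetic iEEG generator that emulates a
    two-stimulus gaze paradigm (1/f background, condition-dependent gamma
    bursts, evoked components, injectable artifacts) so the whole pipeline can
    be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
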