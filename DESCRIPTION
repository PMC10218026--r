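Package: serialdep
Title: Serial Dependence Analysis: Psychometrics, Time-Resolved Decoding and
    Brain-Behavior Linking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for studying perceptual history biases
    (serial dependence) in magnitude perception. Provides a synthetic-data
    generator emulating a two-alternative forced-choice inducer-reference-probe
    experiment and a passive magnitude-stream experiment, lapse-corrected
    cumulative Gaussian psychometric fitting (PSE, JND, Weber fraction) with a
    normalized serial-dependence index and a trial-level logistic regression,
    sliding-window multivariate decoding of past-stimulus information from
    multichannel evoked epochs (pseudo-trial averaging, univariate-ANOVA
    channel selection, leave-one-out linear SVM, shuffled-label empirical
    null, temporal generalization), and a per-window mixed-model regression of
    the behavioral effect on decoding accuracy protected by a cluster-based
    permutation test. Includes the supporting inferential utilities: t tests
    with Cohen's d, Benjamini-Hochberg FDR adjustment, Pearson correlation and
    exact noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
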