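Package: neurolz
Title: Normalized Lempel-Ziv Complexity of Intracranial Recordings Across
    Sleep States and Ketamine Doses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes normalized LZ78 complexity of binarized, band-passed
    electrophysiological signals split into fixed-length epochs, and compares
    the resulting per-epoch complexity values across vigilance states
    (wakefulness, light sleep, slow-wave sleep, REM) and subanaesthetic
    ketamine doses. Inference uses one-way ANOVA with Tukey post-hoc
    contrasts and Cohen's d, plus hierarchical (cat/session) polynomial
    mixed models compared through BIC-approximated Bayes factors to decide
    between linear, quadratic (U or inverted-U) and cubic dose-response or
    state-response shapes. A seeded synthetic electrocorticography generator
    (slow waves, spindle bursts, narrowband gamma, 1/f broadband noise, and a
    direct-value hierarchical mode) provides fully reproducible datasets with
    the same design as the target recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    rlang,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
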