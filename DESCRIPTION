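Package: negshift
Title: Behavioral and Neural Decoding Analyses of Negation on Scalar Adjectives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how the negation operator ("not") modulates the
    representation of scalar adjectives (e.g., "bad"/"good") in behavioral
    mouse-tracking and epoched neurophysiological (MEG-style) data. Implements
    trial filtering and 2x2 repeated-measures ANOVA with partial eta squared,
    per-timepoint regression of mouse trajectories, time-resolved multivariate
    decoding (standardizer, PCA retaining >99% variance, l2 logistic
    regression, stratified cross-validation, ROC AUC and class probability
    estimates), cross-condition generalization from affirmative to negated
    phrases, one-sample sign-flip cluster permutation tests, Morlet wavelet
    time-frequency analysis with percent-baseline correction and beta-band
    condition contrasts, and a decision rule adjudicating among four candidate
    mechanisms (no effect, mitigation, inversion, change). A seeded synthetic
    data generator emulates the factorial phrase design, two-stage trajectory
    dynamics and mechanism-dependent sensor patterns so that every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
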