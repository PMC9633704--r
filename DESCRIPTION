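Package: mmdfc
Title: Intrinsic Dynamics of Functional Connectivity via Meta-Matrix
    Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-resolved (dynamic) functional connectivity analysis for
    parcellated BOLD timeseries. Builds tapered sliding-window correlation
    matrices, the meta-matrix of all pairwise connectivity-pattern
    similarities (functional connectivity dynamics), temporal-decay-of-
    similarity null models and their fit, proximal sub-diagonal transition
    series and distal meta-matrix column profiles, sequence-complexity
    kernels (Shannon entropy, sample entropy, and effort-to-compress via
    non-sequential recursive pair substitution), structure-function dynamic
    similarity against a structural connectome, and proportional-odds
    ordinal regression of per-subject measures against ordered condition
    labels. Includes a synthetic-data generator with piecewise-stationary
    covariance regimes and a planted arousal gradient for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    nnet,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
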