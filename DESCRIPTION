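Package: neurogeom
Title: Neural Population Geometry and Linear Fisher Information Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how learning reshapes neural population codes.
    Estimates stimulus-conditioned response manifolds from trial-by-trial
    population activity (spiking, BOLD or artificial-unit responses), computes
    averaged linear Fisher information (aLFI) and its eigendecomposition form,
    and decomposes training-induced information gain into four geometric
    mechanisms: signal enhancement, manifold shrinkage, signal rotation and
    manifold warping. Includes single-unit metrics (tuning curves, Fano factor,
    noise and signal correlations, threshold-versus-noise interpolation),
    cross-validated linear decoding (Fisher linear discriminant and logistic
    readouts), a moment-based multivariate Poisson log-normal estimator for
    spike counts, and a synthetic population generator with analytically known
    information gains for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
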