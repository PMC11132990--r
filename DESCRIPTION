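Package: rhythmprior
Title: Estimating Rhythm Priors from Iterated Tap Reproduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the iterated-reproduction ("telephone game") paradigm
    used to measure perceptual priors over three-interval rhythms. Provides
    the geometry of the rhythm simplex and its small-integer-ratio category
    sets, preprocessing of tap-onset streams (onset extraction, matching,
    validity filtering, per-iteration averaging), the serial-reproduction
    trial engine, a synthetic Bayesian tapper with a known ground-truth
    prior, kernel density estimation of the prior on a triangular grid,
    constrained Gaussian mixture models anchored at integer-ratio rhythms,
    bootstrap and permutation inference (Jensen-Shannon divergence group
    comparisons, peakiness, integer-ratio overlap, category bias,
    split-half reliability, transmission error, tapping asynchrony), and
    cross-group structure via multidimensional scaling and principal
    component analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
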