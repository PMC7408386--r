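Package: glybench
Title: Benchmarking Normalization Methods for Glycomics Data by Network
    Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates preprocessing strategies for high-throughput glycomics
    abundance tables by a biological measure of quality: after applying a
    candidate normalization, a Gaussian graphical model is inferred from the
    data via shrinkage partial correlations with empirical-null edge
    significance, and the overlap of its edge set with the known glycan
    synthesis pathway is scored by a one-sided Fisher's exact test. Strategies
    are ranked by the bootstrap median of this overlap p-value. Includes
    parsers for glycan composition nomenclature, rule-based construction of
    synthesis pathway priors for subclass-resolved, chromatographic and
    mass-merged platforms, the full menu of standard normalizations
    (total area, median centering, probabilistic quotient, quantile, rank,
    log, per-subclass variants), an age-association secondary evaluation, and
    a synthetic-data generator with known pathway structure and known
    technical artifacts (sample dilution, additive offsets).
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
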