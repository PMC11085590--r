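Package: kinqtl
Title: Kinematic Traits of the Root Elongation Zone and Their QTL
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A quantitative-genetics pipeline for root growth kinematics.
    Fits the flexible logistic velocity model to per-root velocity point
    clouds, derives relative elemental growth rate (REGR) profiles and four
    kinematic traits of the elongation zone, maps quantitative trait loci by
    Haley-Knott regression over hidden-Markov-model genotype probabilities
    with genome-wide permutation thresholds and 1.5-LOD support intervals,
    and relates the kinematic traits to gravitropism tip-angle time courses
    through principal components, maximum swing rate, Pearson correlation,
    and permutation-tested canonical correlation analysis. A synthetic-data
    module simulates a recombinant-inbred-line population with planted QTL
    so the whole pipeline can be exercised and calibrated from scratch.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
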