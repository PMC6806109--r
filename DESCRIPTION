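Package: platespec
Title: Plate-Reader UV-Vis Chemometrics for Edible-Oil Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric workflow for high-throughput UV-Vis optical-density
    spectra acquired on microtiter plate readers, aimed at authenticating
    extra virgin olive oils by producing region and separating them from
    other vegetable oils. Provides spectrum-set containers with tabular
    (CSV) import/export, band trimming and detector-overflow capping,
    multiplicative scatter correction (MSC and EMSC), finite-difference
    derivatives and Savitzky-Golay smoothing, principal component analysis
    with a two-criterion component-count rule, PLS-DA classification via
    NIPALS with repeated stratified k-fold cross-validation, Beer-Lambert
    vertical-pathlength photometry for plate wells versus cuvettes, and a
    seeded generator of pigment-band oil spectra with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
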