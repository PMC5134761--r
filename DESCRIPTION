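Package: lamadapt
Title: Adaptive Local Approximate Models for Torsional Energy Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, evaluates and adaptively refines second-order Local
    Approximate Models (LAMs) of an intramolecular energy surface over
    flexible torsion angles, as used to supply conformational energies
    during crystal structure prediction global searches. Provides
    periodic-aware conformational-space geometry (distances, midpoints,
    regular grids over hyper-rectangular search domains), synthetic
    analytic torsional potentials with harmonically coupled dependent
    degrees of freedom as desk-scale energy oracles, finite-difference
    LAM construction, nearest-model piecewise-quadratic evaluation,
    midpoint-discrepancy adaptive placement in single-pass and iterative
    modes, edge-energy domain expansion, and dense-scan error analysis
    of a LAM set against its oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
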