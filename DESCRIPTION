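Package: ecolandca
Title: Constrained Cellular-Automaton Simulation of Regional Ecological-Land Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating regional land-use change with a constrained
    cellular automaton under alternative ecological-protection policy
    scenarios. A Markov chain projects class-area demands, per-class logistic
    regressions on normalized spatial drivers supply conversion suitability,
    and neighborhood, constraint-mask and stochastic-disturbance factors are
    composed into a synthesis conversion probability applied iteratively until
    class areas reach their demand bands. Includes class-level landscape
    pattern metrics (largest patch index, patch cohesion, splitting index,
    aggregation index), transition-matrix accounting, ESRI ASCII grid I/O and
    a seeded synthetic-landscape generator with known ground truth so the
    whole pipeline is testable without proprietary rasters.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
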