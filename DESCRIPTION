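Package: cochleaR
Title: Frequency-Domain Mechanics of the Implanted Chinchilla Cochlea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale transmission-line model of chinchilla cochlear
    mechanics before and after cochlear-implant electrode insertion. Builds a
    parametric two-duct cochlea with graded basilar-membrane material laws,
    solves the harmonic fluid-partition interaction driven by stapes
    displacement, represents a tapered scala-tympani electrode as a
    position-dependent duct occlusion parameterized by insertion angle, and
    extracts tuning maps (peak location versus frequency, benchmarked against
    the Greenwood frequency-place function) and residual-hearing metrics
    (peak-location shift and peak-magnitude change between healthy and
    implanted runs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
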