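Package: cubecat
Title: Adaptive Block-Game Cognitive Assessment with Entropy-Based Play
    Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational core of a cube-based adaptive cognitive assessment
    battery of six block games (Assembly, Shape-Matching, Sequence-Memory,
    Spatial-Memory, Path-Tracking, Maze). Provides Shannon-entropy and
    co-occurrence-matrix play-complexity measures for game items, autonomous
    item generators that hit a target complexity within a tolerance, a
    rule-based dynamic-difficulty adaptive engine with midpoint reversion,
    fixed and adaptive scoring tables, simulated examinees for in-silico
    validation of the complexity measures, and JSON/YAML session and
    configuration input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
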