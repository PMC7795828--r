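Package: sociability
Title: Context-Aware Sociability Pattern Mining and Social Routine Change Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts time-of-day sociability patterns from timestamped
    social-event streams (e.g., smartphone-sensed conversations), partitioned
    by context attributes such as day of week or weekday/weekend. Patterns are
    mined incrementally from per-slot event counts with a sensitivity-controlled
    candidate filter and adjacency grouping. A windowed Jaccard comparison
    between a persisted reference pattern and fresh observations detects
    abnormal social behavior and social routine changes, optionally judged by a
    Mamdani fuzzy-inference layer with centroid defuzzification that encodes a
    specialist's sensitivity. Includes a synthetic social-event generator with
    planted routines, stability controls and injectable routine changes, plus
    evaluation protocols for routine stability, pattern prediction performance
    and their association.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
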