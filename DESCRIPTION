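Package: discorient
Title: Circular Orientation Analysis for Drifting In Situ Chamber Experiments
Version: 0.1.0
Authors@R:
    person("DISC", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse the orientation of small fish (e.g. glass eels)
    observed one at a time in a free-drifting, rotating circular arena at sea.
    Converts per-second head positions and digital-compass headings into
    magnetic bearings, computes individual and group-level circular statistics
    (mean direction, mean resultant length, Rayleigh uniformity tests with a
    finite-sample correction, confidence arcs), re-expresses bearings relative
    to the moon or sun azimuth from a built-in low-precision ephemeris,
    stratifies results by lunar phase, tide and moon-horizon position,
    contrasts swimming speeds with a Wilcoxon rank-sum test, and simulates
    complete ground-truthed deployments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
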