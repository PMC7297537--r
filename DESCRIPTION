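Package: compassrun
Title: Homing-Excursion Analysis and Axial Circular Statistics for
    GPS-Tracked Free-Roaming Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse homing excursions of GPS-tracked free-roaming
    dogs: reading GPX tracks and trial metadata, local planar projection and
    bearing geometry, excursion detection against a stationary owner,
    turning-trajectory and turning-point location from decile speed profiles,
    measurement of outbound and inbound azimuths including the short
    "compass run" at the start of the return, corridor-based classification
    of returns into tracking, scouting and combined strategies, homing
    efficiency metrics, circular statistics for angular and axial bearing
    samples (mean vectors, Rayleigh test, two-sample Watson's U2, bootstrap
    confidence arcs), solar-azimuth and wind-direction covariate analyses,
    and a synthetic trial generator with ground truth so the whole pipeline
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
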