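Package: smokefence
Title: Person-Specific Time-Stratified Geofences from Kernel Density
    Estimates of Smoking Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds individually tailored geofences around high-risk
    smoking locations from GPS- and time-stamped ecological momentary
    assessment (EMA) self-reports. Smoking events are deduplicated,
    converted to local time and binned into 3-hour intervals; a quartic
    kernel density surface is estimated per participant; mean densities
    are summarised over competing zone partitions (irregular blocks or
    fishnet grids), min-max normalized and classified into risk terciles;
    per-interval geofences are constructed by buffering groups of
    adjacent high-risk zones; and performance is scored as the percent
    of smoking events captured, with threshold sensitivity sweeps and
    partition comparisons. Includes a synthetic EMA-stream generator so
    the whole pipeline is testable without real GPS traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
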