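Package: circact
Title: Circadian Actigraphy Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis battery for circadian wheel-running actigraphy and
    sparsely sampled 24-hour biomarker profiles: nonparametric rhythm
    statistics (interdaily stability, intradaily variability, light-phase
    activity share, activity-bout detection), the Sokolove-Bushell chi-square
    periodogram, activity-onset detection with phase-angle-of-entrainment,
    free-running period, phase-shift, re-entrainment and negative-masking
    estimators, and single-component cosinor regression of 24-hour profiles.
    Includes a light-schedule representation (LD/dim-LD/DD/LL segments, light
    pulses, schedule advances) with Zeitgeber Time conventions, readers and
    writers for common activity-table formats, actogram rendering, and a
    seeded synthetic generator of entrained, fragmented, masked and
    free-running activity series and sinusoidal biomarker profiles so that
    every estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
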