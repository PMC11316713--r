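Package: ultrarhythm
Title: Detection and Energetics of Ultradian Rhythms in Continuous
    Physiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multiple superimposed ultradian rhythms in
    continuously recorded metabolic rate, core body temperature and locomotor
    activity of small mammals. Provides a Morlet continuous wavelet transform
    with shuffle-surrogate significance testing for period detection in the
    ultradian band (0.3-6 h), extraction of individual ultradian bursts with
    period-adapted search windows, partitioning of the daily energy budget into
    resting and ultradian metabolism via a lower-envelope estimate of resting
    metabolic rate, day-by-day period-synchrony analysis, an infrared
    thermography activity index with nest-occupancy scoring, and a synthetic
    multichannel data generator with known ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
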