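Package: respstage
Title: Sleep-Stage Classification from Mask-Sensor Respiration Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate, process and classify respiration voltage
    traces recorded by a wearable (mask-type) triboelectric respiration
    sensor during sleep. Provides a seeded generator of per-stage synthetic
    breathing signals (stage-dependent dominant frequency, amplitude and
    irregularity, snoring vibration, acquisition offset and noise), FFT-based
    respiration-rate and peak-voltage feature extraction over 30-second
    windows, two-step feature scaling (relative output voltage and a
    multiplicative weight on the respiration rate), a nearest-centroid
    sleep-stage classifier fitted by k-means with stage labelling, and
    evaluation utilities (per-stage and averaged accuracy, weight sweeps).
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
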