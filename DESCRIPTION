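Package: bladdermod
Title: Swim-Bladder Modulation Modelling and Acoustic Air-Volume Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the teleost swim bladder as a resonant air volume that
    amplitude-modulates muscle-driven vocalizations, and identifies the air
    volume behind a received call by template matching. Provides a closed-form
    resonant-bubble (Minnaert) model of the bladder, a raised-cosine modulation
    envelope, a synthetic "growl" vocalization generator with WAV input/output,
    and two independent identification methods: blind AM-SSB demodulation with
    short-time Fourier region-of-interest correlation, and cyclostationary
    spectral-correlation analysis with coherent-spectrum templates. Includes an
    in-silico reproduction of a four-volume playback experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
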