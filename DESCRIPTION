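Package: flightloc
Title: Three-Dimensional Acoustic Localization of Nocturnal Flight Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating bird flight calls in three dimensions from a
    small array of time-synchronized microphones using the time difference of
    arrival (TDOA) method. Provides the array-geometry resolution model
    relating sample rate and microphone separation to the attainable lag
    alphabet, band-pass cross-correlation lag estimation, a linearized
    hyperbolic least-squares solver with damped Gauss-Newton refinement and a
    brute-force grid oracle, a synthetic propagation simulator emulating a
    kite-lofted speaker/GPS validation experiment, and error statistics for
    comparing retrievals against a truth track.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
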