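Package: spindlesim
Title: Software Emulation of Muscle Spindles and Their Spiking Afferents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a mammalian muscle spindle as three intrafusal fibers
    (bag1, bag2, nuclear chain) driven by muscle length and gamma fusimotor
    input, producing Group Ia and Group II afferent firing rates, and converts
    those rates into spike trains from populations of noisy Izhikevich Class-1
    sensory neurons. Includes combinational-logic-style single-precision
    arithmetic approximations (fast inverse square root, division and
    quarter-power built from it) mirroring a clock-free digital hardware
    datapath, deterministic stretch-stimulus generators (ramp-and-hold, tap,
    sinusoid, release, triangular, low-pass filtered noise), a suite of classic
    stretch-protocol experiments with spike-train statistics, and plain-text
    readers/writers for waveforms, rate traces and spike rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
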