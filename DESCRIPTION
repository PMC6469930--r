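Package: eodmaps
Title: Active-Sensing and Spatial Analysis of Pallial Spiking in Pulse-Type Electric Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking sparse spiking of pallial (DDi) neurons
    in freely swimming pulse-type weakly electric fish to active electrosensory
    sampling and navigation. Derives instantaneous electric organ discharge
    (EOD) rate from pulse times, blanks EOD artifacts from extracellular
    traces, computes spike-triggered averages of EOD rate, swim speed and
    sampling density with circular-shift permutation nulls, builds occupancy
    and firing-rate maps with Skaggs spatial information and two permutation
    nulls, quantifies swim-direction preference, and accumulates egocentric
    spike- and position-triggered landmark matrices (STLM/PTLM) yielding
    landmark-presence probability maps and anterior-posterior / left-right
    preference vectors. A seeded synthetic-session generator (arena,
    correlated-random-walk trajectory, inhomogeneous gamma-renewal EOD train,
    modulated point-process spike trains) provides ground truth for
    parameter-recovery and null-calibration testing of every stage.
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
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
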