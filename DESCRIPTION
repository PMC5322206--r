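Package: eccperiod
Title: Periodized Isokinetic Eccentric Strength Training: Prescription,
    Progression Analytics, and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prescribing and monitoring periodized eccentric
    strength training on an isokinetic dynamometer. Implements eccentric
    peak-torque estimation from concentric testing, visual torque-target
    compliance bands, an intra-session fatigue classifier driving a +/-5
    percent workload-adjustment rule, initial and revised macrocycle plan
    builders with session scheduling, torque-time curve processing
    (gravity correction, repetition segmentation, interval variability,
    total work and mean power), progression analytics (indexed total
    work, rolling slope windows, plateau and decline detection, recovery
    placement), and a virtual-participant simulator for closed-loop
    testing of the full method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
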