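Package: skiphase
Title: Ground-Contact Events and Inner-Cycle Phases in Roller-Ski
    Skating from a Single Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects pole and ski ground-contact events and the derived
    inner-cycle phases (contact time, flight time) in roller-ski skating
    from a single trunk-mounted inertial measurement unit.  Force-pole and
    force-insole channels are thresholded into reference events; a
    per-timestep LSTM sequence classifier is trained under a
    leave-one-subject-out protocol on the six raw IMU channels at 100 Hz;
    predicted contact sequences are cleaned by run-length block filtering;
    and an event-matching engine attributes detections to reference
    events, counting missed and extra events and summarising timing and
    phase errors per subject and pooled.  A synthetic-trial generator
    emulates cyclic skating laps with phase-locked force and IMU
    waveforms so that the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
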