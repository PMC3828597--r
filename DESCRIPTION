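Package: vibrissa
Title: Quasi-Static Mechanics of Tapered Whiskers Contacting a Pole
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Planar quasi-static mechanics of rodent facial whiskers
    (vibrissae) interacting with a cylindrical pole. Models a whisker as a
    truncated elastic cone with intrinsic parabolic curvature and solves the
    large-deflection Euler-Bernoulli contact problem as a boundary-value
    problem by iterative shooting. Continues solution branches in push angle,
    detects saddle-node (slip-off) and tip-release (pull-off) detachments,
    maps detachment curves in the push-angle/object-distance plane, and
    simulates quasi-static rotation sweeps emulating galvo experiments.
    Includes analysis of tracked whisker medial-axis shapes (base-angle and
    push-angle estimation, projected-arclength correction, effective-length
    calibration) and a seeded synthetic fixture generator so the analysis
    chain is testable without video data.
License: MIT
Encoding: UTF-8
NeedsCompilation: yes
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
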