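Package: antennaCPG
Title: Central Pattern Generator Model of Insect Antennal Tactile Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates rhythmic tactile exploration movements of the stick
    insect head-antenna system with a two-level central pattern generator
    (CPG): a chain of five phase-coupled Hopf oscillators generates rhythm,
    amplitude and offset for each joint, while truncated Fourier
    pattern-formation networks shape the periodic waveform of each joint
    angle. Drive signals actuate a three degree-of-freedom kinematic chain
    (neck yaw plus two slanted antennal hinge joints per side) through
    rate-limited velocity servos. Includes a synthetic generator of
    quasi-rhythmic joint-angle recordings, sliding cross-correlogram and
    circular-statistics analysis of inter-joint phase coupling, and a
    config-driven experiment layer covering proprioceptor-ablation and
    phase-lead sweep protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
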