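Package: cpgcoord
Title: Bilateral Locomotor CPG Model with Persistent-Sodium Half-Center
    Rhythm Generators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a reduced bilateral locomotor central pattern
    generator: two flexor-extensor half-center rhythm generators with
    persistent-sodium (INaP) bursting dynamics, reciprocal flexor-flexor
    and crossed extensor-flexor commissural inhibition, and a
    drive-coupling rule by which the excitatory drive to each flexor
    half-center simultaneously inhibits the ipsilateral extensor
    half-center.  Provides burst detection, cycle and phase metrics,
    activity-mode classification, drive sweeps, two-parameter frequency
    and coordination-regime maps (including bistability probing from
    multiple initial conditions), interlimb 1:n phase-locking analysis,
    and split-belt-like asymmetric drive experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
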