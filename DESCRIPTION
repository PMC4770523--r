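Package: acpabm
Title: Agent-Based Simulation of Advance Care Planning Behavior Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic agent-based model of advance care planning (ACP)
    adoption built on the Transtheoretical Model's stages of change.
    Agents on a toroidal grid accrue ACP propensity points from life-event
    patches (a personal ICU stay, a loved one's critical illness, primary
    care visits) and from same-cell social interactions that pull
    lower-stage agents up and drag higher-stage agents down, with
    threshold-triggered stage advancement, backsliding, and an immutable
    susceptibility trait. Ships the two published experiment presets, a
    replicate runner with outcome summaries, and an exact Markov-chain
    oracle for validating the stochastic engine under teleport movement.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
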