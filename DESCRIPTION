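Package: pincontrol
Title: Pin-Controller and Inverted-Pendulum Analysis of Quiet-Standing
    Posturography
Version: 0.1.0
Authors@R:
    person("pincontrol", "developers", email = "pincontrol@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of bipedal quiet standing recorded on
    two parallel force plates. Implements a unilaterally-constrained
    "pin-controller" variant of the single-segment inverted pendulum, in
    which one limb contributes a fixed centre of pressure (a pin) while the
    contralateral limb performs the corrective centre-of-pressure motion.
    Provides a delayed proportional-derivative sway simulator emitting
    per-plate wrenches and marker trajectories; centre-of-pressure
    extraction from force-plate wrenches including projection onto elevated
    support planes; segmental whole-body centre-of-mass estimation with
    zero-phase filtering and double differentiation; per-limb kinetic and
    kinematic inverted-pendulum correlation statistics; and Fisher-z
    aggregation of correlation coefficients into group summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
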