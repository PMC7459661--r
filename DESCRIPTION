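Package: burnoutSD
Title: Stock-and-Flow Simulation of Burnout Development and Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A system-dynamics toolkit for simulating the development of and
    recovery from occupational burnout. Provides a generic declarative
    stock-and-flow engine (Euler integration, first-order smoothing,
    goal-seeking stocks, piecewise-linear table functions, signed feedback-loop
    enumeration), a simplified capacity-effort-demands illustration model, a
    full burnout model with five named feedback loops and persona-controllable
    learning dynamics, trajectory pattern analytics (burnout-episode counting,
    peak and settling detection, trajectory classification), and a seeded
    generator of synthetic retrospective burnout sketches with
    build-up/crash/recovery phase segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
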