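Package: rulechoice
Title: Simulated Operant Choice Between Rules on Concurrent
    Variable-Interval Schedules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A programmable operant-conditioning task engine for studying
    rule-governed versus contingency-shaped choice.  Implements
    constant-probability variable-interval (VI) schedules generated by the
    Fleshler-Hoffman progression, concurrent VI-extinction pairs with a
    changeover delay, multiple-schedule sessions with training, rule-test
    and choice-test phases, simulated agents (rule-following and
    reinforcement-rate learning) standing in for human participants, and
    the matching analysis stack: response-allocation measures, stability
    criteria, and the Fisher-Pitman paired exact permutation test.
    Sessions are fully seeded and emit timestamped CSV event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
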