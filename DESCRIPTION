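Package: adhersim
Title: Monte Carlo Simulation of Adaptive SMS Support for Medication Adherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates daily medication-taking in a cohort of chronically ill
    patients whose adherence is governed by three multiplicative barriers
    (doubts about disease severity, concerns about the medication, and
    forgetfulness), and compares four text-message selection strategies:
    fixed reminders, random messages, baseline-survey tailoring, and a
    LinUCB contextual bandit that learns each patient's true barriers from
    daily pill-cap feedback. Includes stress-test scenarios with misreported
    barriers, a mid-course barrier change, and message fatigue, plus tools
    for aggregating replicated runs and exporting trajectory tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
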