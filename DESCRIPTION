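Package: jadadr
Title: Choosing Between Discordant Systematic Reviews with the Jadad Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with discordant systematic reviews: a
    deterministic, parameterizable implementation of the 1997 Jadad
    hierarchical decision algorithm (Steps A-I) for selecting the "best
    evidence" systematic review among overlapping reviews with
    meta-analysis; a classifier of pooled effect estimates into
    favourable, null, or unfavourable verdicts; replication-agreement
    statistics over paired assessments (choice agreement, final-step
    agreement, effect-direction concordance, ease and time summaries); a
    bundled corpus of 21 published discordant-review cases with recorded
    author and replicator assessments; and a synthetic-case simulator
    that quantifies how divergent operationalizations of the algorithm's
    tie-breaking rules produce selection disagreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
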