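Package: chatflow
Title: Dialog-Graph Engine for Scripted Mental-Health Support Chatbots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based conversational-agent toolkit built around a typed
    directed dialog graph: a hand-authorable YAML content format with a
    structural validator and Graphviz export, a deterministic turn-traversal
    engine with per-user session state, keyword intent classification with
    priority-intent digressions and a fixed self-harm escalation protocol,
    privacy-preserving event logging with pre/post single-item outcome
    summaries, and a synthetic open-trial simulator for exercising the full
    pipeline without any real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
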