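Package: deepexplain
Title: Deep Temporal Active Inference Agents That Explain Their Own Actions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-level (deep temporal) discrete active-inference
    agent that solves a T-maze by minimising expected free energy, is then
    queried in simple language about why it made its first or second move,
    and answers by inference over counterfactual explanations. Provides
    exact categorical probability primitives, a factorised POMDP engine with
    structured variational state inference, expected free energy (risk plus
    ambiguity) policy evaluation, a hierarchical narrative level that passes
    empirical priors between epochs, the full T-maze-with-language task
    model, and scripted experiments reproducing belief replay and
    confabulation phenomena.
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
    optparse
Config/testthat/edition: 3
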