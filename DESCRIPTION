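Package: causalbn
Title: Causal Reasoning on Discrete Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis testing on causal Bayesian networks over discrete
    variables. Given a fixed network topology (read from SIF or TGF files)
    and possibly incomplete observations, conditional probability tables are
    learned by expectation-maximisation with multiple restarts; exact
    posterior inference uses the variable elimination algorithm; external
    interventions (fixed-value do-assignments, edge additions and removals)
    are evaluated by graph mutilation, and counterfactual questions by the
    twin-network construction. Continuous measurements are discretised by a
    family of rounding, thresholding and quantile (bracket medians,
    Pearson-Tukey) methods. A compact query language exposes posterior,
    interventional and counterfactual queries from code or a command line.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
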