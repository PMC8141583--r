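Package: aesval
Title: Motivation-Gated Reinforcement Learning of Aesthetic Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the acquisition of aesthetic biases by
    motivation-gated reinforcement learning over two-dimensional sensory
    stimuli (visual balance and complexity).  Provides four value
    functions (linear, output-saturation, component-saturation, and a
    Gaussian-complexity form), two parameter-update rules (the
    gradient-based delta rule and a shortest-path rule that projects onto
    the target isoline of the value function), a stochastic world model
    for stimuli, rewards and motivation, a 16-condition experiment
    crossing reward models with value functions and update rules, and
    trajectory statistics (convergence time, recovery time, final regret,
    final free parameters, deviation from straightness) with ANOVA,
    post-hoc t-test and Kendall correlation comparisons across
    conditions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
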