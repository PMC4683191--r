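Package: banditdbm
Title: Bayesian Learning and Decision-Policy Inference for Two-Armed Bandit
    Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits a Dynamic Belief Model (DBM) of non-stationary Bayesian
    reward-rate learning to trial-level two-armed bandit choice data, and
    classifies each subject's decision policy among five candidates
    (Win-Stay/Lose-Shift, epsilon-Greedy, tau-Switch, Softmax, Knowledge
    Gradient) by marginal likelihood. Group-level learning parameters
    (stability gamma and prior reward expectation r) are estimated by
    maximal marginal likelihood over a discrete lattice, with policy
    identity and policy parameters integrated out by deterministic
    quadrature. Includes a synthetic-cohort simulator for the bandit task
    (games of Bernoulli arms with Beta-distributed reward rates), parameter
    recovery experiments, and the downstream group-comparison statistics
    (surface-moment confidence intervals, contingency tests, two-sample
    t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
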