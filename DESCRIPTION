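Package: nsabandit
Title: Neural Selection Agreement Agents for Non-Stationary Multi-Armed Bandits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulator for non-stationary K-armed Bernoulli bandit problems and a
    minimal two-population rate-network decision agent (the neural selection
    agreement model). Provides four concept-drift environment variants
    (piecewise stationary, drifting, sinusoidal, partially sinusoidal),
    reference bandit algorithms (Thompson sampling, UCB1, epsilon-greedy,
    random), pseudo-regret and sliding-window selection-entropy analytics,
    Welch/Bonferroni algorithm comparison, and a covariance-matrix-adaptation
    evolution strategy for fitting the agent's 22 hyperparameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
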