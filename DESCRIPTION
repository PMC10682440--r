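Package: bcgrmc
Title: Impulsive BCG Dosing Regimens by Multiobjective Control and
    Koopman Model Predictive Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a four-state tumor-immune model of intravesical
    Bacillus Calmette-Guerin (BCG) immunotherapy with impulsive drug
    instillations; searches optimal (dose, gap, count) regimens by
    minimizing a multiobjective cost with particle swarm, simulated
    annealing and ant colony metaheuristics; fits a data-driven lifted
    linear surrogate (extended dynamic mode decomposition with delay
    embedding and thin-plate radial basis functions) and runs impulsive
    receding-horizon control on it; and quantifies regimen robustness
    with Monte Carlo uncertainty analysis and variance-based (Sobol)
    sensitivity indices of the tumor settling time.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
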