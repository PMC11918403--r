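Package: ordval
Title: Hierarchical Bayesian Modeling of Risk and Ambiguity Attitudes with
    Ordinal Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling decision-making under uncertainty when
    outcomes are qualitative (ordinal) as well as quantitative. Implements
    hierarchical Bayesian subjective-value models (classic power utility,
    estimated ordinal values, and a no-subjective-parameters baseline) with
    logistic and trembling-hand choice rules, fitted by MCMC with
    rank-normalized split R-hat and bulk effective-sample-size diagnostics.
    Includes Pareto-smoothed importance-sampling leave-one-out
    cross-validation (PSIS-LOO) with stacking weights for model comparison,
    a task-design generator and choice simulator for model-recovery studies,
    participant exclusion rules, and Bayesian robust (Student-t) regression
    with highest-density intervals for cross-domain comparison of ambiguity
    attitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rjags,
    coda,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
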