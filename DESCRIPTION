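Package: irsabc
Title: Coalescent ABC Reconstruction of Mosquito Effective Population Size
    Across Indoor Residual Spraying Rounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs fluctuations in the effective population size (Ne)
    of Anopheles gambiae across indoor-residual-spraying (IRS) cycles from
    temporally spaced microsatellite samples.  Provides a heterochronous
    piecewise-constant-Ne coalescent simulator with a generalized stepwise
    microsatellite mutation model, the standard one- and two-sample
    microsatellite summary statistics (unbiased expected heterozygosity,
    mean number of alleles, allele-size variance, Garza-Williamson M,
    Weir-Cockerham FST), approximate Bayesian computation with rejection and
    multinomial-logistic scenario choice over six competing Ne-trajectory
    scenarios, generation-clock model comparison, a synthetic-data module
    that emulates the study's sampling design, GenePop input/output, and the
    density-dependent stage-structured projection model used to assess
    rainfall-shock explanations for Ne crashes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    nnet,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
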