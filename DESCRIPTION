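Package: gxebias
Title: Bias in Gene-Environment Interaction Estimates Under Case Contamination
Version: 0.1.0
Authors@R:
    person("gxebias", "developers", email = "gxebias@example.org",
           role = c("aut", "cre"))
Description: Closed-form approximations to the bias in gene-environment
    interaction (GxE) coefficients estimated by logistic regression when
    clinically diagnosed cases are contaminated by a nuisance pathologic
    state whose frequency varies with the environment. Provides exact
    probability computations for the underlying risk models, an exact
    pseudo-true-parameter oracle for the misspecified clinical-diagnosis
    fit under retrospective case-control sampling, a retrospective
    case-control simulator with latent pathologic states, simulation
    experiments comparing empirical, theoretical and approximate
    coefficient values, and a per-SNP bias screen with fixed-point bias
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
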