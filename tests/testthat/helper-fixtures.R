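# Shared fixtures: the frozen simulation-setting parameter sets and small
# random-model generators used across the suite.

cov_gxz <- function() {
  covariate_distribution(genotype_model(0.10, "raw_bernoulli"),
                         env_freq = 0.14, covariate_freqs = c(0.50, 0.52))
}

cov_gx <- function() {
  covariate_distribution(genotype_model(0.10, "raw_bernoulli"),
                         env_freq = 0.14)
}

setting_a_model <- function(betaGxX = 0, betaZ1 = 0) {
  disease_model("binary_with_contamination",
                B = c(-1, -0.41, log(8), betaGxX),
                Z_effects = c(betaZ1, -0.08),
                contamination = contamination_spec(0.36, 0.06))
}

setting_b_model <- function(n_z = 2) {
  disease_model("trinomial",
                B = c(-1, -0.69, 1.3, 1.099),
                B_star = c(-1.7, 0, 0.5, 0),
                Z_effects = if (n_z == 2) c(0.10, -0.083) else numeric())
}

# contamination-free variant: the nuisance state has zero mass
setting_b_clean <- function(n_z = 2) {
  disease_model("trinomial",
                B = c(-1, -0.69, 1.3, 1.099),
                B_star = c(-Inf, 0, 0, 0),
                Z_effects = if (n_z == 2) c(0.10, -0.083) else numeric())
}

rand_B <- function(scale = 2) runif(4, -scale, scale)

rand_trinomial <- function(scale = 2, n_z = 0) {
  disease_model("trinomial", B = rand_B(scale), B_star = rand_B(scale),
                Z_effects = runif(n_z, -scale / 2, scale / 2))
}

rand_cov <- function(n_z = 0) {
  covariate_distribution(genotype_model(runif(1, 0.05, 0.5)),
                         env_freq = runif(1, 0.1, 0.9),
                         covariate_freqs = runif(n_z, 0.2, 0.8))
}

# feasible random binary-with-contamination model: rejection-samples until
# every cell satisfies p1 <= 1 - S(x)
rand_binary <- function(scale = 1.5, n_z = 0, cov = NULL) {
  repeat {
    S <- contamination_spec(runif(1, 0, 0.5), runif(1, 0, 0.5))
    m <- try(disease_model("binary_with_contamination", B = rand_B(scale),
                           Z_effects = runif(n_z, -scale / 2, scale / 2),
                           contamination = S), silent = TRUE)
    if (inherits(m, "try-error")) next
    ok <- !is.null(cov) &&
      !inherits(try(cell_probabilities(m, cov), silent = TRUE), "try-error")
    if (is.null(cov) || ok) return(m)
  }
}
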