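# JSON (de)serialization of model configurations.  Keys mirror the
# constructor arguments; all rates are decimals (0.36, not 36%).

#' Write a model configuration to JSON
#'
#' @param model A [disease_model()].
#' @param cov A [covariate_distribution()].
#' @param design Optional [study_design()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, cov, design = NULL, path) {
  cfg <- list(
    model = list(kind = model$kind,
                 B = as.list(model$B),
                 Z_effects = model$Z_effects),
    covariates = list(genotype = list(theta = cov$genotype$theta,
                                      coding = cov$genotype$coding),
                      env_freq = cov$env_freq,
                      covariate_freqs = cov$covariate_freqs))
  if (!is.null(model$B_star)) {
    bs <- as.list(model$B_star)
    # JSON has no -Inf; encode the degenerate no-nuisance intercept as a string
    bs <- lapply(bs, function(v) if (is.infinite(v)) "-Inf" else v)
    cfg$model$B_star <- bs
    cfg$model$Z_effects_star <- model$Z_effects_star
  }
  if (!is.null(model$contamination)) {
    cfg$model$contamination <- list(S0 = model$contamination$S0,
                                    S1 = model$contamination$S1)
  }
  if (!is.null(design)) {
    cfg$design <- list(n_controls = design$n_controls,
                       n_cases = design$n_cases,
                       replicates = design$replicates, seed = design$seed)
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a model configuration from JSON
#'
#' @param path Path to a config written by [write_model_config()] (or
#'   hand-authored with the same keys).
#' @return List with components `model` ([disease_model()]),
#'   `cov` ([covariate_distribution()]) and `design` ([study_design()] or
#'   `NULL`).
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mc <- cfg$model
  contamination <- if (!is.null(mc$contamination)) {
    contamination_spec(mc$contamination$S0, mc$contamination$S1)
  }
  B_star <- if (!is.null(mc$B_star)) {
    vapply(mc$B_star, function(v) {
      if (identical(v, "-Inf")) -Inf else as.numeric(v)
    }, numeric(1))[paste0(COEF_NAMES, "_star")]
  }
  model <- disease_model(
    kind = mc$kind,
    B = as.numeric(unlist(mc$B[COEF_NAMES])),
    B_star = B_star,
    Z_effects = if (is.null(mc$Z_effects)) numeric() else
      as.numeric(mc$Z_effects),
    Z_effects_star = if (is.null(mc$Z_effects_star)) NULL else
      as.numeric(mc$Z_effects_star),
    contamination = contamination)
  cc <- cfg$covariates
  cov <- covariate_distribution(
    genotype_model(cc$genotype$theta, cc$genotype$coding),
    env_freq = cc$env_freq,
    covariate_freqs = if (is.null(cc$covariate_freqs)) numeric() else
      as.numeric(cc$covariate_freqs))
  design <- if (!is.null(cfg$design)) {
    study_design(cfg$design$n_controls, cfg$design$n_cases,
                 replicates = cfg$design$replicates %||% 500L,
                 seed = cfg$design$seed %||% 1L)
  }
  list(model = model, cov = cov, design = design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
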