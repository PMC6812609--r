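# Simulation experiments: fit the misspecified clinical logistic model to
# simulated retrospective datasets and compare empirical averages against the
# pseudo-true oracle and both closed-form approximations, per the built-in
# Settings A-D presets.

#' Fit the clinical-diagnosis logistic model
#'
#' Maximum-likelihood logistic regression of the clinical status `dcl` on the
#' requested terms.  The latent `d_true` column, when present, is ignored.
#'
#' @param data A dataset from [simulate_dataset()] (or any data frame with
#'   columns `dcl`, `g`, `x`, and optionally `z1`, ...).
#' @param fitted_terms Character subset of
#'   `c("intercept", "G", "X", "GxX", "Z1", ...)`; default all available.
#' @return A [gamma_vector()] with provenance `"mle"` and attributes `se`
#'   (standard errors, named by term), `converged` and `separated` (fit
#'   flagged as separated/unstable).
#' @export
fit_clinical_logistic <- function(data, fitted_terms = NULL) {
  zcols <- grep("^z[0-9]+$", names(data), value = TRUE)
  n_z <- length(zcols)
  available <- all_terms(n_z)
  if (is.null(fitted_terms)) fitted_terms <- available
  stopifnot(all(fitted_terms %in% available), "intercept" %in% fitted_terms)
  X <- design_matrix(data, fitted_terms)
  fit <- suppressWarnings(
    glm.fit(X, data$dcl, family = stats::binomial()))
  cf <- fit$coefficients
  se <- rep(NA_real_, length(cf))
  ok <- fit$converged && all(is.finite(cf))
  if (ok) {
    W <- fit$weights
    H <- crossprod(X, X * W)
    V <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(diag(V))
  }
  separated <- !ok || any(abs(cf) > 15) || any(!is.finite(se))
  full <- stats::setNames(rep(0, 4 + n_z), all_terms(n_z))
  full[fitted_terms] <- ifelse(is.finite(cf), cf, 0)
  out <- gamma_vector(full["intercept"], full["G"], full["X"], full["GxX"],
                      gammaZ = full[setdiff(names(full),
                                            c("intercept", "G", "X", "GxX"))],
                      provenance = "mle")
  attr(out, "se") <- stats::setNames(se, fitted_terms)
  attr(out, "converged") <- fit$converged
  attr(out, "separated") <- separated
  attr(out, "terms") <- fitted_terms
  out
}

#' Built-in simulation setting presets
#'
#' Frozen parameter sets of the package's simulation experiments.
#' * `"A"`: binary model with contamination; `beta0 = -1`, `betaG = -0.41`,
#'   `betaX = log(8)`, `betaZ1 = 0` (adjustable), `betaZ2 = -0.08`,
#'   `S = (0.36, 0.06)`; the interaction `betaGxX` runs over the grid
#'   `log(1) .. log(8)`; 3,000 cases and 3,000 controls.  With `betaZ1 >=
#'   0.5` the top of the grid becomes infeasible under the per-cell
#'   perfect-sensitivity mechanism (one cell needs `p1 > 1 - S(1)`); the
#'   runner flags such grid points rather than failing the run.
#' * `"B"`: trinomial model; `B = (-1, -0.69, 1.3, 1.099)`,
#'   `B* = (-1.7, 0, 0.5, 0)`, shared Z effects `(0.10, -0.083)`; 3,000/3,000.
#' * `"C"`: as B with 1,000 controls and 2,000 cases.
#'
#' Covariates in all settings: G Bernoulli(0.10), X Bernoulli(0.14),
#' Z1 Bernoulli(0.50) (age, median split), Z2 Bernoulli(0.52) (sex).
#'
#' @param name `"A"`, `"B"` or `"C"`.
#' @param betaZ1 Setting-A age effect (0, 0.5, 1 or 1.5 in the reference
#'   experiments; default 0).
#' @return List with components `label`, `model`, `cov`, `design`,
#'   `grid` (data frame of grid values, possibly 1 row), `grid_param`.
#' @export
setting_preset <- function(name = c("A", "B", "C"), betaZ1 = 0) {
  name <- match.arg(name)
  cov <- covariate_distribution(genotype_model(0.10, "raw_bernoulli"),
                                env_freq = 0.14,
                                covariate_freqs = c(0.50, 0.52))
  if (name == "A") {
    model <- disease_model("binary_with_contamination",
                           B = c(-1, -0.41, log(8), 0),
                           Z_effects = c(betaZ1, -0.08),
                           contamination = contamination_spec(0.36, 0.06))
    list(label = "A", model = model, cov = cov,
         design = study_design(3000, 3000, replicates = 500L),
         grid = data.frame(betaGxX = log(c(1, 2, 4, 8))),
         grid_param = "betaGxX")
  } else {
    model <- disease_model("trinomial",
                           B = c(-1, -0.69, 1.3, 1.099),
                           B_star = c(-1.7, 0, 0.5, 0),
                           Z_effects = c(0.10, -0.083))
    n0 <- if (name == "C") 1000L else 3000L
    n1 <- if (name == "C") 2000L else 3000L
    list(label = name, model = model, cov = cov,
         design = study_design(n0, n1, replicates = 500L),
         grid = data.frame(betaGxX = model$B["betaGxX"], row.names = NULL),
         grid_param = "betaGxX")
  }
}

set_model_param <- function(model, param, value) {
  if (param %in% names(model$B)) {
    model$B[param] <- value
  } else if (!is.null(model$B_star) && param %in% names(model$B_star)) {
    model$B_star[param] <- value
  } else stop("unknown grid parameter: ", param, call. = FALSE)
  model
}

#' Run a simulation setting
#'
#' For each grid point: simulates `replicates` retrospective datasets, fits
#' the clinical logistic model to each, and tabulates the empirical mean and
#' SD of every coefficient next to the pseudo-true oracle value and the
#' theoretical and linearized closed-form values.  Separated or
#' non-convergent fits are dropped and counted; if they exceed 1% of the
#' replicates the run errors.
#'
#' @param setting A preset name (`"A"`, `"B"`, `"C"`) or a list as returned
#'   by [setting_preset()] (allowing custom grids).
#' @param replicates,n_controls,n_cases,seed Optional overrides of the preset
#'   design.
#' @param include_Z Fit the Z main effects (default TRUE; set FALSE for
#'   saturated no-Z theory checks).
#' @param grid Optional replacement grid (data frame with the preset's grid
#'   parameter as column).
#' @return Data frame of class `gxe_experiment_table`: one row per grid point
#'   and coefficient with columns `setting`, `grid_param`, `grid_value`,
#'   `term`, `empirical_mean`, `empirical_sd`, `oracle`, `theoretical`,
#'   `linearized`, `n0`, `n1`, `R`, `n_dropped`, `feasible`.
#' @export
run_setting <- function(setting, replicates = NULL, n_controls = NULL,
                        n_cases = NULL, seed = NULL, include_Z = TRUE,
                        grid = NULL) {
  preset <- if (is.character(setting)) setting_preset(setting) else setting
  design <- preset$design
  if (!is.null(replicates)) design$replicates <- as.integer(replicates)
  if (!is.null(n_controls)) design$n_controls <- as.integer(n_controls)
  if (!is.null(n_cases)) design$n_cases <- as.integer(n_cases)
  if (!is.null(seed)) design$seed <- as.integer(seed)
  if (!is.null(grid)) preset$grid <- grid
  n_z <- n_covariates(preset$cov)
  fitted_terms <- if (include_Z) all_terms(n_z) else
    c("intercept", "G", "X", "GxX")
  cf <- design$n_cases / (design$n_cases + design$n_controls)
  R <- design$replicates
  terms_gamma <- term_to_gamma(fitted_terms)

  out <- list()
  for (i in seq_len(nrow(preset$grid))) {
    value <- preset$grid[[preset$grid_param]][i]
    model_i <- set_model_param(preset$model, preset$grid_param, value)
    feasible <- tryCatch({ cell_probabilities(model_i, preset$cov); TRUE },
                         error = function(e) FALSE)
    if (!feasible) {
      warning(sprintf("grid point %s = %.4g is infeasible; skipped",
                      preset$grid_param, value), call. = FALSE)
      out[[i]] <- data.frame(
        setting = preset$label, grid_param = preset$grid_param,
        grid_value = value, term = terms_gamma,
        empirical_mean = NA_real_, empirical_sd = NA_real_,
        oracle = NA_real_, theoretical = NA_real_, linearized = NA_real_,
        n0 = design$n_controls, n1 = design$n_cases, R = R,
        n_dropped = NA_integer_, feasible = FALSE)
      next
    }
    oracle <- pseudo_true_gamma(
      pseudo_true_problem(model_i, preset$cov, cf, fitted_terms))
    apx <- approx_gamma(model_i)
    draws <- matrix(NA_real_, R, length(terms_gamma),
                    dimnames = list(NULL, terms_gamma))
    dropped <- 0L
    for (r in seq_len(R)) {
      dat <- simulate_dataset(model_i, preset$cov, design, r)
      fit <- fit_clinical_logistic(dat, fitted_terms)
      if (attr(fit, "separated")) { dropped <- dropped + 1L; next }
      draws[r, ] <- as.numeric(fit)[match(terms_gamma, names(fit))]
    }
    if (dropped > 0.01 * R) {
      stop(sprintf("%d of %d replicates dropped (separation) at %s = %.4g",
                   dropped, R, preset$grid_param, value), call. = FALSE)
    }
    keep <- stats::complete.cases(draws)
    out[[i]] <- data.frame(
      setting = preset$label, grid_param = preset$grid_param,
      grid_value = value, term = terms_gamma,
      empirical_mean = colMeans(draws[keep, , drop = FALSE]),
      empirical_sd = apply(draws[keep, , drop = FALSE], 2, stats::sd),
      oracle = as.numeric(oracle)[match(terms_gamma, names(oracle))],
      theoretical = as.numeric(apx$theoretical)[
        match(terms_gamma, names(apx$theoretical))],
      linearized = as.numeric(apx$linearized)[
        match(terms_gamma, names(apx$linearized))],
      n0 = design$n_controls, n1 = design$n_cases, R = R,
      n_dropped = dropped, feasible = TRUE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  class(res) <- c("gxe_experiment_table", class(res))
  res
}

default_misspec_offsets <- function(delta = 0.05) {
  data.frame(scenario = c("reference", "both_up", "both_down", "differential"),
             s0 = c(0, delta, -delta, delta),
             s1 = c(0, delta, -delta, -delta))
}

#' Contamination misspecification study
#'
#' Quantifies how the assumed clinical-fit limit shifts when the analyst's
#' contamination rates are off by a fixed amount while the data-generating
#' truth is unchanged.  The base setting is projected to its
#' binary-with-contamination form (coefficients of the disease of interest
#' plus the induced contamination rates) and the pseudo-true oracle is
#' re-solved under each offset scenario via [sensitivity_sweep()].  The three
#' default scenarios are both rates overestimated by `delta`, both
#' underestimated by `delta`, and a differential shift (`S(0) + delta`,
#' `S(1) - delta`) that widens the contamination gap.
#'
#' @param setting Preset name (default `"C"`) or [setting_preset()] list.
#' @param offsets Data frame of scenarios (columns `scenario`, `s0`, `s1`);
#'   default the three reference scenarios with `delta`.
#' @param delta Offset magnitude for the default scenarios.
#' @param include_Z Include Z terms in the fitted model.
#' @return The [sensitivity_sweep()] table.
#' @export
misspecification_study <- function(setting = "C",
                                   offsets = default_misspec_offsets(delta),
                                   delta = 0.05, include_Z = TRUE) {
  preset <- if (is.character(setting)) setting_preset(setting) else setting
  model <- preset$model
  cov <- preset$cov
  if (model$kind == "trinomial") {
    rates <- derive_population_rates(model, cov)
    model <- disease_model("binary_with_contamination", B = model$B,
                           Z_effects = model$Z_effects,
                           contamination = contamination_spec(
                             rates$S_induced[["S0"]], rates$S_induced[["S1"]]))
  }
  cf <- preset$design$n_cases /
    (preset$design$n_cases + preset$design$n_controls)
  n_z <- n_covariates(cov)
  fitted_terms <- if (include_Z) all_terms(n_z) else
    c("intercept", "G", "X", "GxX")
  problem <- pseudo_true_problem(model, cov, cf, fitted_terms)
  sensitivity_sweep(problem, offsets)
}
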