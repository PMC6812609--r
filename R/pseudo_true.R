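# Exact large-sample limit of the misspecified clinical-diagnosis logistic
# fit under retrospective case-control sampling.  Because all covariates are
# binary the population reduces to <= 2^(2+K) cells; the pseudo-true
# coefficients are the minimizer of the expected logistic negative
# log-likelihood over the sampling law, found by Newton iteration.

all_terms <- function(n_z) c("intercept", "G", "X", "GxX",
                             if (n_z) paste0("Z", seq_len(n_z)))

term_to_gamma <- function(terms) {
  map <- c(intercept = "gamma0", G = "gammaG", X = "gammaX", GxX = "gammaGxX")
  ifelse(terms %in% names(map), map[terms], sub("^Z", "gammaZ", terms))
}

design_matrix <- function(cells, terms) {
  cols <- lapply(terms, function(tm) {
    switch(tm,
           intercept = rep(1, nrow(cells)),
           G = cells$g, X = cells$x, GxX = cells$g * cells$x,
           cells[[tolower(tm)]])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Pseudo-true-parameter problem
#'
#' Bundles a true disease model, covariate distribution, retrospective
#' sampling fraction and the terms of the (possibly misspecified) clinical
#' logistic model to be fitted.
#'
#' @param model A [disease_model()].
#' @param cov A [covariate_distribution()].
#' @param case_fraction Sampling fraction of clinical cases,
#'   `n1 / (n0 + n1)`, in `(0, 1)`.
#' @param fitted_terms Character subset of
#'   `c("intercept", "G", "X", "GxX", "Z1", ...)`; must contain
#'   `"intercept"`.  Default: all terms available.
#' @return An object of class `gxe_pseudo_true_problem`.
#' @export
pseudo_true_problem <- function(model, cov, case_fraction = 0.5,
                                fitted_terms = NULL) {
  stopifnot(inherits(model, "gxe_model"), inherits(cov, "gxe_covariates"))
  if (!is.numeric(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
    stop("`case_fraction` must lie in (0, 1)", call. = FALSE)
  }
  available <- all_terms(n_covariates(cov))
  if (is.null(fitted_terms)) fitted_terms <- available
  if (!all(fitted_terms %in% available)) {
    stop("unknown fitted terms: ",
         paste(setdiff(fitted_terms, available), collapse = ", "),
         call. = FALSE)
  }
  if (!"intercept" %in% fitted_terms) {
    stop("`fitted_terms` must include the intercept", call. = FALSE)
  }
  structure(list(model = model, cov = cov, case_fraction = case_fraction,
                 fitted_terms = fitted_terms),
            class = "gxe_pseudo_true_problem")
}

#' Exact pseudo-true clinical-model coefficients
#'
#' Computes the probability limit of the maximum-likelihood logistic fit of
#' the clinical diagnosis on the requested terms, under retrospective
#' sampling with the given case fraction.  The sampling law places mass
#' `case_fraction * pr(cell | DCL = 1)` on case rows and
#' `(1 - case_fraction) * pr(cell | DCL = 0)` on control rows; the expected
#' negative log-likelihood is convex and is minimized by Newton iteration
#' with step halving from the zero vector until the gradient max-norm falls
#' below `tol`.
#'
#' @param problem A [pseudo_true_problem()].
#' @param tol Gradient max-norm tolerance.
#' @param max_iter Iteration cap; hitting it raises a warning (e.g. under
#'   separation, when some fitted cell pattern carries mass for only one
#'   outcome) and returns the capped iterate.
#' @return A [gamma_vector()] with provenance `"oracle"` and attributes
#'   `iterations`, `grad_norm`, `converged` and `terms`.
#' @export
pseudo_true_gamma <- function(problem, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(problem, "gxe_pseudo_true_problem"))
  cp <- cell_probabilities(problem$model, problem$cov)
  pi1 <- sum(cp$mass * cp$p_dcl1)
  if (pi1 <= 0 || pi1 >= 1) {
    stop(sprintf("degenerate clinical prevalence pr(DCL=1) = %.3g", pi1),
         call. = FALSE)
  }
  cf <- problem$case_fraction
  w1 <- cf * cp$mass * cp$p_dcl1 / pi1
  w0 <- (1 - cf) * cp$mass * (1 - cp$p_dcl1) / (1 - pi1)
  X <- design_matrix(cp, problem$fitted_terms)
  XX <- rbind(X, X)
  w <- c(w1, w0)
  y <- rep(c(1, 0), each = nrow(X))
  keep <- w > 0
  XX <- XX[keep, , drop = FALSE]; w <- w[keep]; y <- y[keep]

  nll <- function(gma) {
    u <- drop(XX %*% gma)
    sum(w * (log1p(exp(-abs(u))) + pmax(u, 0) - y * u))
  }
  gma <- rep(0, ncol(XX))
  obj <- nll(gma)
  it <- 0L
  g_norm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    u <- drop(XX %*% gma)
    mu <- plogis(u)
    grad <- drop(crossprod(XX, w * (mu - y)))
    g_norm <- max(abs(grad))
    H <- crossprod(XX, XX * (w * mu * (1 - mu)))
    step <- tryCatch(solve(H, grad), error = function(e) grad)
    # backtracking guards the global phase only: once the gradient is small
    # the objective decrease is below machine precision and the full Newton
    # step is taken (local quadratic convergence region)
    lambda <- 1
    if (g_norm > 1e-6) {
      while (lambda > 2^-20) {
        ocand <- nll(gma - lambda * step)
        if (is.finite(ocand) && ocand <= obj) break
        lambda <- lambda / 2
      }
    }
    gma <- gma - lambda * step
    obj <- nll(gma)
    # terminate on step size: quadratic convergence drives the step to
    # machine precision even when tiny-mass cells make H ill-conditioned
    if (max(abs(lambda * step)) < 1e-13 * (1 + max(abs(gma)))) break
  }
  u <- drop(XX %*% gma)
  g_norm <- max(abs(drop(crossprod(XX, w * (plogis(u) - y)))))
  converged <- g_norm <= tol
  if (!converged) {
    warning(sprintf(
      "oracle Newton capped at %d iterations (grad norm %.2e); possible separation",
      max_iter, g_norm), call. = FALSE)
  }
  full <- stats::setNames(rep(0, 4 + n_covariates(problem$cov)),
                          all_terms(n_covariates(problem$cov)))
  full[problem$fitted_terms] <- gma
  out <- gamma_vector(full["intercept"], full["G"], full["X"], full["GxX"],
                      gammaZ = full[setdiff(names(full), c("intercept", "G",
                                                           "X", "GxX"))],
                      provenance = "oracle")
  attr(out, "iterations") <- it
  attr(out, "grad_norm") <- g_norm
  attr(out, "converged") <- converged
  attr(out, "terms") <- problem$fitted_terms
  out
}

#' Oracle sensitivity to assumed contamination rates
#'
#' Re-solves the pseudo-true problem over a grid of offsets applied to the
#' contamination rates of a binary-with-contamination model, reporting each
#' coefficient and its delta from the unperturbed reference.  This is the
#' deterministic backbone of the misspecification experiments: equal offsets
#' to `S(0)` and `S(1)` preserve how differential the contamination is and
#' perturb the coefficients far less than offsets that widen the
#' `S(0) - S(1)` gap.
#'
#' @param problem A [pseudo_true_problem()] whose model kind is
#'   `"binary_with_contamination"`.
#' @param offsets Data frame (or 2-column matrix) with columns `s0`, `s1` of
#'   additive offsets, optionally a `scenario` label column; or a numeric
#'   vector of offsets applied to both rates.
#' @return Data frame, one row per scenario and coefficient, with columns
#'   `scenario`, `s0_offset`, `s1_offset`, `S0`, `S1`, `term`, `gamma`,
#'   `delta` (gamma minus its reference value).
#' @export
sensitivity_sweep <- function(problem, offsets) {
  stopifnot(inherits(problem, "gxe_pseudo_true_problem"))
  model <- problem$model
  if (model$kind != "binary_with_contamination") {
    stop("sensitivity_sweep requires a binary_with_contamination model; ",
         "project a trinomial model first (see misspecification_study)",
         call. = FALSE)
  }
  if (is.numeric(offsets) && is.null(dim(offsets))) {
    offsets <- data.frame(s0 = offsets, s1 = offsets)
  }
  offsets <- as.data.frame(offsets)
  stopifnot(all(c("s0", "s1") %in% names(offsets)))
  if (is.null(offsets$scenario)) {
    offsets$scenario <- sprintf("s0%+g_s1%+g", offsets$s0, offsets$s1)
  }
  ref <- pseudo_true_gamma(problem)
  S <- model$contamination
  rows <- lapply(seq_len(nrow(offsets)), function(i) {
    S_new <- contamination_spec(S$S0 + offsets$s0[i], S$S1 + offsets$s1[i])
    m_new <- disease_model("binary_with_contamination", B = model$B,
                           Z_effects = model$Z_effects,
                           contamination = S_new)
    p_new <- pseudo_true_problem(m_new, problem$cov, problem$case_fraction,
                                 problem$fitted_terms)
    g <- pseudo_true_gamma(p_new)
    data.frame(scenario = offsets$scenario[i],
               s0_offset = offsets$s0[i], s1_offset = offsets$s1[i],
               S0 = S_new$S0, S1 = S_new$S1,
               term = names(ref), gamma = as.numeric(g),
               delta = as.numeric(g) - as.numeric(ref),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
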