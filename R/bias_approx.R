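# Closed-form approximations to the clinical-model coefficients Gamma induced
# by the two true-model settings, in both the exact log-contrast
# ("theoretical") form and the first-order ("linearized") form, plus the
# null-preservation remarks as predicates and inversion of the linearized map
# for bias correction.

# log(S + exp(a)), stable for large |a| and for a = -Inf.
log_s_plus_exp <- function(S, a) {
  out <- numeric(length(a))
  a <- rep_len(a, length(out)); S <- rep_len(S, length(out))
  hi <- a > 0
  out[hi] <- a[hi] + log1p(S[hi] * exp(-a[hi]))
  out[!hi] <- log(S[!hi] + exp(a[!hi]))
  out
}

# log(exp(a) + exp(b)), tolerating -Inf arguments.
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- ifelse(is.infinite(m) & m < 0, -Inf,
                m + log1p(exp(-abs(a - b))))
  out
}

validate_model1_inputs <- function(B, S) {
  B <- named_coefs(check_coef(B, "B"), "B")
  if (!inherits(S, "gxe_contamination")) {
    stopifnot(is.numeric(S), length(S) == 2L)
    S <- contamination_spec(S[1], S[2])
  }
  list(B = B, S = S)
}

#' Clinical-model coefficients under the binary model with contamination
#'
#' Evaluates the induced clinical-diagnosis coefficients when the true risk
#' model is the binary logistic model for `D = 1` and the clinical label is
#' contaminated at rate `S(x)` per environmental stratum.  Two forms are
#' returned: the exact log-contrast (`theoretical`) of the clinical log-odds
#' `log{(S(x) + e^eta) / (1 - S(x))}`, and the first-order (`linearized`)
#' expressions in which the term carrying each coefficient is expanded around
#' zero, e.g. `gammaG = e^beta0 / (e^beta0 + S(0)) * betaG`.
#'
#' With `S(0) = S(1) = 0` both forms return `B` exactly (no contamination, no
#' bias).
#'
#' @param B Coefficients `(beta0, betaG, betaX, betaGxX)` of the true model.
#' @param S A [contamination_spec()] or numeric `c(S0, S1)`.
#' @param Z_effects Effects of non-interacting covariates; their induced
#'   coefficients are approximated by the same pattern with `S(0)` (see the
#'   methods vignette).
#' @return List with components `theoretical` and `linearized`, each a
#'   [gamma_vector()].
#' @examples
#' approx_gamma_model1(B = c(-1, -0.41, 2.1, 0), S = c(0.36, 0.06))
#' @export
approx_gamma_model1 <- function(B, S, Z_effects = numeric()) {
  v <- validate_model1_inputs(B, S)
  B <- v$B; S0 <- v$S$S0; S1 <- v$S$S1
  Z_effects <- check_coef(Z_effects, "Z_effects")
  b0 <- B[1]; bG <- B[2]; bX <- B[3]; bGX <- B[4]

  th <- gamma_vector(
    gamma0  = log_s_plus_exp(S0, b0) - log1p(-S0),
    gammaG  = log_s_plus_exp(S0, b0 + bG) - log_s_plus_exp(S0, b0),
    gammaX  = log_s_plus_exp(S1, b0 + bX) - log1p(-S1) -
              log_s_plus_exp(S0, b0) + log1p(-S0),
    gammaGxX = log_s_plus_exp(S1, b0 + bX + bG + bGX) -
               log_s_plus_exp(S1, b0 + bX) -
               log_s_plus_exp(S0, b0 + bG) + log_s_plus_exp(S0, b0),
    gammaZ = vapply(Z_effects, function(bz) {
      log_s_plus_exp(S0, b0 + bz) - log_s_plus_exp(S0, b0)
    }, numeric(1)),
    provenance = "theoretical")

  e0 <- exp(b0)
  lin <- gamma_vector(
    gamma0  = log1p(S0) - log1p(-S0) + b0 / (1 + S0),
    gammaG  = e0 / (e0 + S0) * bG,
    gammaX  = log_s_plus_exp(S1, b0) - log1p(-S1) -
              log_s_plus_exp(S0, b0) + log1p(-S0) +
              e0 / (e0 + S1) * bX,
    gammaGxX = log_s_plus_exp(S1, b0 + bX + bG) -
               log_s_plus_exp(S1, b0 + bX) -
               log_s_plus_exp(S0, b0 + bG) + log_s_plus_exp(S0, b0) +
               exp(b0 + bX + bG) / (S1 + exp(b0 + bX + bG)) * bGX,
    gammaZ = e0 / (e0 + S0) * Z_effects,
    provenance = "linearized")
  list(theoretical = th, linearized = lin)
}

#' Clinical-model coefficients under the trinomial model
#'
#' Evaluates the induced clinical-diagnosis coefficients when the disease of
#' interest and the nuisance state follow a multinomial logit with coefficient
#' vectors `B` and `B_star`.  The clinical log-odds in a cell are exactly
#' `log(e^eta + e^eta*)`, so the `theoretical` form is the corresponding
#' log-sum contrast, e.g.
#' `gammaG = log(e^{beta0+betaG} + e^{beta0*+betaG*}) - log(e^{beta0} + e^{beta0*})`,
#' and the `linearized` form carries each coefficient through a first-order
#' weight, e.g. `gammaG = e^{beta0} / (e^{beta0} + e^{beta0*+betaG*}) * betaG`.
#'
#' @param B Coefficients of the disease of interest.
#' @param B_star Coefficients of the nuisance state (`beta0*` may be `-Inf`
#'   for the degenerate no-nuisance model, in which case both forms reduce to
#'   `B`).
#' @param Z_effects,Z_effects_star Non-interacting covariate effects for the
#'   two states; `Z_effects_star` defaults to `Z_effects` (shared).
#' @return List with components `theoretical` and `linearized`, each a
#'   [gamma_vector()].
#' @examples
#' approx_gamma_model2(B = c(-1, -0.69, 1.3, 1.099),
#'                     B_star = c(-1.7, 0, 0.5, 0))
#' @export
approx_gamma_model2 <- function(B, B_star, Z_effects = numeric(),
                                Z_effects_star = Z_effects) {
  B <- named_coefs(check_coef(B, "B"), "B")
  B_star <- named_coefs(check_coef(B_star, "B_star",
                                   allow_minf_intercept = TRUE), "B_star")
  Z_effects <- check_coef(Z_effects, "Z_effects")
  Z_effects_star <- check_coef(Z_effects_star, "Z_effects_star")
  stopifnot(length(Z_effects_star) == length(Z_effects))
  b0 <- B[1]; bG <- B[2]; bX <- B[3]; bGX <- B[4]
  c0 <- B_star[1]; cG <- B_star[2]; cX <- B_star[3]; cGX <- B_star[4]

  th <- gamma_vector(
    gamma0  = lse2(b0, c0),
    gammaG  = lse2(b0 + bG, c0 + cG) - lse2(b0, c0),
    gammaX  = lse2(b0 + bX, c0 + cX) - lse2(b0, c0),
    gammaGxX = lse2(b0 + bG + bX + bGX, c0 + cG + cX + cGX) -
               lse2(b0 + bX, c0 + cX) - lse2(b0 + bG, c0 + cG) +
               lse2(b0, c0),
    gammaZ = vapply(seq_along(Z_effects), function(k) {
      lse2(b0 + Z_effects[k], c0 + Z_effects_star[k]) - lse2(b0, c0)
    }, numeric(1)),
    provenance = "theoretical")

  # first-order weights w = e^{a} / (e^{a} + e^{b}) computed as plogis(a - b)
  lin <- gamma_vector(
    gamma0  = if (is.infinite(c0)) b0 else c0 + 1 / (1 + exp(c0)) * b0,
    gammaG  = plogis(b0 - (c0 + cG)) * bG,
    gammaX  = plogis(b0 - (c0 + cX)) * bX,
    gammaGxX = lse2(b0 + bG + bX, c0 + cG + cX + cGX) -
               lse2(b0 + bX, c0 + cX) - lse2(b0 + bG, c0 + cG) +
               lse2(b0, c0) +
               plogis((b0 + bG + bX) - (c0 + cG + cX + cGX)) * bGX,
    gammaZ = plogis(b0 - (c0 + Z_effects_star)) * Z_effects,
    provenance = "linearized")
  list(theoretical = th, linearized = lin)
}

#' Approximate clinical coefficients for a disease model
#'
#' Dispatches to [approx_gamma_model1()] or [approx_gamma_model2()] according
#' to the model kind.
#'
#' @param model A [disease_model()].
#' @return List with `theoretical` and `linearized` [gamma_vector()]s.
#' @export
approx_gamma <- function(model) {
  stopifnot(inherits(model, "gxe_model"))
  if (model$kind == "binary_with_contamination") {
    approx_gamma_model1(model$B, model$contamination, model$Z_effects)
  } else {
    approx_gamma_model2(model$B, model$B_star, model$Z_effects,
                        model$Z_effects_star)
  }
}

#' Per-coefficient bias report
#'
#' Tabulates, per coefficient, the true value, both induced-coefficient forms
#' and the biases `Gamma - B`.
#'
#' @param model A [disease_model()].
#' @return Data frame with columns `coefficient`, `true_beta`,
#'   `gamma_theoretical`, `gamma_linearized`, `bias_theoretical`,
#'   `bias_linearized`.
#' @export
bias_report <- function(model) {
  g <- approx_gamma(model)
  truth <- c(model$B, model$Z_effects)
  nz <- length(model$Z_effects)
  data.frame(
    coefficient = c(COEF_NAMES, if (nz) paste0("betaZ", seq_len(nz))),
    true_beta = as.numeric(truth),
    gamma_theoretical = as.numeric(g$theoretical),
    gamma_linearized = as.numeric(g$linearized),
    bias_theoretical = as.numeric(g$theoretical) - as.numeric(truth),
    bias_linearized = as.numeric(g$linearized) - as.numeric(truth),
    row.names = NULL)
}

remark_tol <- 1e-10

#' Null-preservation remarks as predicates
#'
#' Each reported remark about which null coefficients survive the
#' misspecified clinical fit is evaluated as a predicate on the linearized
#' formulas: the remark's premise is *imposed* on a copy of the supplied
#' parameters (e.g. `betaG <- 0`) and the conclusion (`gammaG == 0`) checked,
#' so every remark is testable from any starting configuration.  Rows with
#' `universal = FALSE` are the cautionary "might not be zero" observations;
#' for those `holds = TRUE` records that a nonzero induced coefficient was
#' indeed produced from the supplied parameters.
#'
#' @param model_kind `"model1"` (binary with contamination) or `"model2"`
#'   (trinomial).
#' @param B True coefficients `(beta0, betaG, betaX, betaGxX)`.
#' @param B_star_or_S For `"model1"` a [contamination_spec()] (or numeric
#'   `c(S0, S1)`); for `"model2"` the nuisance-state coefficients.
#' @return Data frame with columns `remark_id`, `description`, `universal`,
#'   `holds`.
#' @export
remarks_predicates <- function(model_kind = c("model1", "model2"), B,
                               B_star_or_S) {
  model_kind <- match.arg(model_kind)
  B <- named_coefs(check_coef(B, "B"), "B")
  out <- list()
  add <- function(id, description, universal, holds) {
    out[[length(out) + 1]] <<- data.frame(
      remark_id = id, description = description,
      universal = universal, holds = holds)
  }
  zero <- function(x) all(abs(x) <= remark_tol)

  if (model_kind == "model1") {
    v <- validate_model1_inputs(B, B_star_or_S)
    S <- v$S
    lin <- function(B2, S2) approx_gamma_model1(B2, S2)$linearized
    th <- function(B2, S2) approx_gamma_model1(B2, S2)$theoretical
    g0 <- approx_gamma_model1(B, c(0, 0))
    add("m1_no_contamination",
        "S(0) = S(1) = 0 implies Gamma = B (both forms)", TRUE,
        zero(g0$linearized - B) && zero(g0$theoretical - B))
    Bg <- B; Bg["betaG"] <- 0
    add("m1_null_G", "betaG = 0 implies gammaG = 0", TRUE,
        zero(lin(Bg, S)["gammaG"]))
    Bgi <- Bg; Bgi["betaGxX"] <- 0
    add("m1_null_G_and_GxX",
        "betaG = betaGxX = 0 implies gammaG = gammaGxX = 0", TRUE,
        zero(lin(Bgi, S)[c("gammaG", "gammaGxX")]))
    Snd <- contamination_spec(S$S0, S$S0)
    Bx <- B; Bx["betaX"] <- 0
    add("m1_nondiff_null_X",
        "nondifferential S and betaX = 0 imply gammaX = 0", TRUE,
        zero(lin(Bx, Snd)["gammaX"]))
    Ball <- B; Ball[c("beta0", "betaG", "betaX", "betaGxX")] <- 0
    add("m1_nondiff_all_null",
        "nondifferential S and beta0 = betaX = betaG = betaGxX = 0 imply gammaGxX = 0",
        TRUE, zero(lin(Ball, Snd)["gammaGxX"]))
    # cautionary observations: null effects whose estimate may be biased
    add("m1_null_G_biased_intercept",
        "betaG = 0 need not give gamma0 = beta0", FALSE,
        !zero(lin(Bg, S)["gamma0"] - Bg["beta0"]))
    add("m1_null_X_may_bias",
        "betaX = 0 need not give gammaX = 0 (differential S)", FALSE,
        { BxS <- B; BxS["betaX"] <- 0; !zero(lin(BxS, S)["gammaX"]) })
    add("m1_null_GxX_may_bias",
        "betaGxX = 0 need not give gammaGxX = 0", FALSE,
        { Bi <- B; Bi["betaGxX"] <- 0; !zero(lin(Bi, S)["gammaGxX"]) })
  } else {
    Bs <- named_coefs(check_coef(B_star_or_S, "B_star",
                                 allow_minf_intercept = TRUE), "B_star")
    names(Bs) <- paste0(COEF_NAMES, "_star")
    lin <- function(B2, Bs2) approx_gamma_model2(B2, Bs2)$linearized
    th <- function(B2, Bs2) approx_gamma_model2(B2, Bs2)$theoretical
    B0 <- B; B0["beta0"] <- 0; Bs0 <- Bs; Bs0["beta0_star"] <- 0
    add("m2_null_intercepts",
        "beta0 = beta0* = 0 implies gamma0 = 0 (linearized form)", TRUE,
        zero(lin(B0, Bs0)["gamma0"]))
    Bg <- B; Bg["betaG"] <- 0; Bsg <- Bs; Bsg["betaG_star"] <- 0
    add("m2_null_G", "betaG = betaG* = 0 implies gammaG = 0 (both forms)",
        TRUE, zero(lin(Bg, Bsg)["gammaG"]) && zero(th(Bg, Bsg)["gammaG"]))
    Bx <- B; Bx["betaX"] <- 0; Bsx <- Bs; Bsx["betaX_star"] <- 0
    add("m2_null_X", "betaX = betaX* = 0 implies gammaX = 0 (both forms)",
        TRUE, zero(lin(Bx, Bsx)["gammaX"]) && zero(th(Bx, Bsx)["gammaX"]))
    Bgi <- Bg; Bgi["betaGxX"] <- 0
    Bsgi <- Bsg; Bsgi["betaGxX_star"] <- 0
    add("m2_null_G_and_GxX",
        "betaG = betaG* = betaGxX = betaGxX* = 0 imply gammaG = gammaGxX = 0",
        TRUE, zero(lin(Bgi, Bsgi)[c("gammaG", "gammaGxX")]))
    B6 <- B; B6[c("betaG", "betaX", "betaGxX")] <- 0
    Bs6 <- Bs; Bs6[c("betaG_star", "betaX_star", "betaGxX_star")] <- 0
    add("m2_all_six_null",
        "all of betaG, betaG*, betaX, betaX*, betaGxX, betaGxX* zero imply gammaGxX = 0",
        TRUE, zero(lin(B6, Bs6)["gammaGxX"]))
  }
  do.call(rbind, out)
}

#' Invert the linearized bias map for correction
#'
#' Solves `gamma_linearized(B) = gamma_hat` for the true coefficients `B`
#' given the contamination assumptions (binary model) or nuisance-state
#' coefficients (trinomial model), by damped Newton iteration with a
#' numerical Jacobian, starting at `B = gamma_hat`.  Also returns the plug-in
#' bias estimate, i.e. the linearized approximation evaluated at `gamma_hat`
#' itself: `gamma_linearized(gamma_hat) - gamma_hat`.  The two corrections
#' coincide to first order; their disagreement is a useful diagnostic for how
#' far the linearization is being pushed.
#'
#' @param gamma_hat Fitted clinical-model coefficients: a [gamma_vector()] or
#'   named/plain numeric of length `4 + K`.
#' @param model_kind `"model1"` or `"model2"`.
#' @param S Contamination assumptions (model 1).
#' @param B_star,Z_effects_star Nuisance-state assumptions (model 2).
#' @param n_z Number of trailing covariate coefficients in `gamma_hat`.
#' @param solve_for Names of the coefficients to solve for (subset of
#'   `beta0, betaG, betaX, betaGxX, betaZ1, ...`); the rest are fixed at
#'   their `gamma_hat` values as plug-ins.  Default: all.  Fixing the
#'   intercept (and covariates) is appropriate when `gamma_hat` comes from a
#'   retrospective fit, whose intercept absorbs the sampling ratio and must
#'   not be pushed through the prospective bias map.
#' @param max_iter,tol Iteration cap and residual tolerance (max-abs of
#'   `gamma(B) - gamma_hat` over the solved components).
#' @return List with `corrected` (named numeric, `beta*` scale), `converged`,
#'   `iterations`, `residual`, and `plug_in_bias` (named by gamma
#'   coefficient).
#' @export
invert_bias <- function(gamma_hat, model_kind = c("model1", "model2"),
                        S = NULL, B_star = NULL, Z_effects_star = NULL,
                        n_z = NULL, solve_for = NULL, max_iter = 100L,
                        tol = 1e-10) {
  model_kind <- match.arg(model_kind)
  g <- as.numeric(gamma_hat)
  if (is.null(n_z)) n_z <- length(g) - 4L
  stopifnot(length(g) == 4L + n_z)
  beta_names <- c(COEF_NAMES, if (n_z) paste0("betaZ", seq_len(n_z)))
  if (is.null(solve_for)) solve_for <- beta_names
  stopifnot(all(solve_for %in% beta_names))
  idx <- match(solve_for, beta_names)
  if (model_kind == "model1") {
    if (is.null(S)) stop("model1 inversion requires `S`", call. = FALSE)
    if (!inherits(S, "gxe_contamination")) S <- contamination_spec(S[1], S[2])
    fwd <- function(b) as.numeric(
      approx_gamma_model1(b[1:4], S, Z_effects = b[seq_len(n_z) + 4])$linearized)
  } else {
    if (is.null(B_star)) stop("model2 inversion requires `B_star`",
                              call. = FALSE)
    if (is.null(Z_effects_star)) Z_effects_star <- rep(0, n_z)
    fwd <- function(b) as.numeric(
      approx_gamma_model2(b[1:4], B_star, Z_effects = b[seq_len(n_z) + 4],
                          Z_effects_star = Z_effects_star)$linearized)
  }

  b <- g
  resid <- function(b) (fwd(b) - g)[idx]
  res <- resid(b)
  it <- 0L
  while (max(abs(res)) > tol && it < max_iter) {
    it <- it + 1L
    # forward-difference Jacobian over the solved components
    J <- matrix(0, length(idx), length(idx))
    h <- 1e-7
    for (j in seq_along(idx)) {
      bp <- b; bp[idx[j]] <- bp[idx[j]] + h
      J[, j] <- (resid(bp) - res) / h
    }
    step <- tryCatch(solve(J, res), error = function(e) res)  # damped FP fallback
    lambda <- 1
    repeat {
      b_new <- b; b_new[idx] <- b[idx] - lambda * step
      res_new <- tryCatch(resid(b_new), error = function(e) NULL)
      if (!is.null(res_new) && all(is.finite(res_new)) &&
          (max(abs(res_new)) < max(abs(res)) || lambda < 1 / 64)) break
      lambda <- lambda / 2
    }
    b <- b_new; res <- res_new
  }
  converged <- max(abs(res)) <= tol
  if (!converged) {
    stop(sprintf(
      "bias inversion did not converge in %d iterations (residual %.3e)",
      max_iter, max(abs(res))), call. = FALSE)
  }
  plug_in <- fwd(g) - g
  names(b) <- beta_names
  names(plug_in) <- c(GAMMA_NAMES, if (n_z) paste0("gammaZ", seq_len(n_z)))
  list(corrected = b, converged = converged, iterations = it,
       residual = max(abs(res)), plug_in_bias = plug_in,
       solved_for = solve_for)
}
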