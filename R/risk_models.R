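#' gxebias: bias in G-by-E estimates when a clinical case might not be the case
#'
#' Tools for quantifying the bias incurred when a logistic regression of a
#' *clinical* diagnosis on genotype, environment and their interaction is used
#' as a stand-in for the model of the *pathologic* (true) disease state, and
#' the clinically diagnosed cases contain a nuisance pathologic state whose
#' frequency varies with the environment (differential outcome
#' misclassification).
#'
#' The package implements two true-model settings: a binary risk model with a
#' specified contamination rate per environmental stratum, and a trinomial
#' (multinomial-logit) model with separate coefficient vectors for the disease
#' of interest and the nuisance state.  For both it provides closed-form
#' theoretical (log-contrast) and linearized approximations to the induced
#' clinical-model coefficients, an exact pseudo-true-parameter oracle under
#' retrospective case-control sampling, a data simulator, simulation
#' experiment drivers, and a per-SNP bias screen.
#'
#' @keywords internal
#' @importFrom stats dbinom glm.fit binomial plogis pchisq pnorm rbinom
#' @importFrom utils read.csv write.csv modifyList
"_PACKAGE"

COEF_NAMES <- c("beta0", "betaG", "betaX", "betaGxX")
GAMMA_NAMES <- c("gamma0", "gammaG", "gammaX", "gammaGxX")

#' Hardy-Weinberg genotype probabilities
#'
#' Genotype frequencies at a biallelic locus with minor-allele frequency
#' `theta` under Hardy-Weinberg equilibrium.
#'
#' @param theta Minor-allele frequency, in `[0, 1]`.
#' @return Named numeric vector `c(AA, Aa, aa)` summing to 1:
#'   `((1 - theta)^2, 2 theta (1 - theta), theta^2)`.
#' @examples
#' hwe_probabilities(0.1)
#' @export
hwe_probabilities <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("`theta` must be a single number in [0, 1]", call. = FALSE)
  }
  c(AA = (1 - theta)^2, Aa = 2 * theta * (1 - theta), aa = theta^2)
}

#' Genotype model for a biallelic SNP
#'
#' Describes how the binary genotype indicator used in the risk models is
#' derived from a biallelic locus.  With `raw_bernoulli` the indicator is
#' Bernoulli with frequency `theta` directly (the default used in the
#' simulation experiments, mimicking a SNP carrier indicator with frequency
#' 0.10).  `dominant_carrier` codes carriers of at least one minor allele
#' (frequency `1 - (1 - theta)^2` under HWE); `recessive` codes minor-allele
#' homozygotes (frequency `theta^2`).
#'
#' @param theta Allele (or indicator) frequency in `[0, 1]`.
#' @param coding One of `"raw_bernoulli"`, `"dominant_carrier"`, `"recessive"`.
#' @return An object of class `gxe_genotype`.
#' @seealso [hwe_probabilities()]
#' @export
genotype_model <- function(theta,
                           coding = c("raw_bernoulli", "dominant_carrier",
                                      "recessive")) {
  coding <- match.arg(coding)
  hwe_probabilities(theta)  # validates theta
  structure(list(theta = theta, coding = coding), class = "gxe_genotype")
}

#' Frequency of the binary genotype indicator
#'
#' @param gm A [genotype_model()].
#' @return Probability that the genotype indicator equals 1.
#' @export
genotype_freq <- function(gm) {
  stopifnot(inherits(gm, "gxe_genotype"))
  switch(gm$coding,
         raw_bernoulli    = gm$theta,
         dominant_carrier = 1 - (1 - gm$theta)^2,
         recessive        = gm$theta^2)
}

#' Joint covariate distribution
#'
#' Joint law of the genotype indicator G, environment indicator X, and
#' additional non-interacting binary covariates Z_k.  All components are
#' independent, so the support is the `2^(2+K)` cells of indicator
#' combinations.
#'
#' @param genotype A [genotype_model()].
#' @param env_freq Frequency of `X = 1`, in `[0, 1]`.
#' @param covariate_freqs Numeric vector of frequencies for the Z covariates
#'   (possibly empty).
#' @return An object of class `gxe_covariates`.
#' @examples
#' covariate_distribution(genotype_model(0.10), env_freq = 0.14,
#'                        covariate_freqs = c(0.50, 0.52))
#' @export
covariate_distribution <- function(genotype, env_freq,
                                   covariate_freqs = numeric()) {
  stopifnot(inherits(genotype, "gxe_genotype"))
  freqs <- c(env_freq, covariate_freqs)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  structure(list(genotype = genotype, env_freq = env_freq,
                 covariate_freqs = as.numeric(covariate_freqs)),
            class = "gxe_covariates")
}

n_covariates <- function(cov) length(cov$covariate_freqs)

#' Enumerate the covariate support
#'
#' @param cov A [covariate_distribution()].
#' @return Data frame with one row per cell: columns `g`, `x`, `z1`, ...,
#'   and `mass` (cell probability; sums to 1).
#' @export
enumerate_cells <- function(cov) {
  stopifnot(inherits(cov, "gxe_covariates"))
  K <- n_covariates(cov)
  znames <- if (K) paste0("z", seq_len(K)) else character()
  vars <- c(list(g = 0:1, x = 0:1),
            stats::setNames(rep(list(0:1), K), znames))
  cells <- expand.grid(vars, KEEP.OUT.ATTRS = FALSE)
  freqs <- c(genotype_freq(cov$genotype), cov$env_freq, cov$covariate_freqs)
  mass <- rep(1, nrow(cells))
  for (j in seq_along(freqs)) {
    mass <- mass * ifelse(cells[[j]] == 1, freqs[j], 1 - freqs[j])
  }
  cells$mass <- mass
  cells
}

#' Contamination rates per environmental stratum
#'
#' `S(x) = pr(D != 1 | DCL = 1, X = x)`: the probability that a clinically
#' diagnosed case is not a true case of interest, by environment stratum.
#' `tau(x) = 1 - S(x)` is the frequency of the true diagnosis within the
#' clinically diagnosed set.  Controls are assumed clean:
#' `pr(D = 0 | DCL = 0) = 1`.
#'
#' @param S0,S1 Contamination rates for `X = 0` and `X = 1`, each in `[0, 1)`.
#' @return An object of class `gxe_contamination` with fields `S0`, `S1`.
#' @examples
#' contamination_spec(S0 = 0.36, S1 = 0.06)  # ApoE e4- / e4+ rates
#' @export
contamination_spec <- function(S0, S1) {
  for (s in c(S0, S1)) {
    if (!is.finite(s) || s < 0 || s >= 1) {
      stop("contamination rates must lie in [0, 1); S(x) = 1 means every ",
           "clinical case is nuisance", call. = FALSE)
    }
  }
  structure(list(S0 = S0, S1 = S1), class = "gxe_contamination")
}

tau_of <- function(S, x) 1 - ifelse(x == 1, S$S1, S$S0)

check_coef <- function(b, what, allow_minf_intercept = FALSE) {
  b <- as.numeric(b)
  bad <- !is.finite(b)
  if (allow_minf_intercept) bad[1] <- bad[1] && !identical(b[1], -Inf)
  if (any(bad)) stop(what, " must be finite", call. = FALSE)
  if (any(abs(b[is.finite(b)]) > 20)) {
    stop(what, " has |coefficient| > 20; rejected as unphysical on the ",
         "log-odds scale", call. = FALSE)
  }
  b
}

named_coefs <- function(b, what = "B") {
  b <- as.numeric(b)
  if (length(b) != 4L) stop(what, " must have 4 coefficients ",
                            "(intercept, G, X, GxX)", call. = FALSE)
  names(b) <- COEF_NAMES
  b
}

#' True disease risk model
#'
#' Two settings are supported.  `kind = "binary_with_contamination"` is the
#' binary model: the true state of interest `D = 1` versus everything else,
#' with log-odds `beta0 + betaG g + betaX x + betaGxX g x (+ betaZ z)`, and a
#' clinical label contaminated at rate `S(x)` (see Details).
#' `kind = "trinomial"` specifies the disease of interest (`D = 1`) and the
#' nuisance state (`D = 1*`) by a multinomial logit against healthy (`D = 0`),
#' with coefficient vectors `B` and `B_star`; the contamination rate is then
#' induced, not specified.
#'
#' @details
#' For the binary model the clinical-label mechanism is perfect sensitivity
#' (every true case is clinically diagnosed) plus per-cell false positives
#' calibrated so that `pr(D != 1 | DCL = 1, g, x, z) = S(x)` holds exactly in
#' every covariate cell, giving `pr(DCL = 1 | cell) = p1 / (1 - S(x))`.  A
#' cell with `p1 > 1 - S(x)` is infeasible and raises an error.
#'
#' The `B_star` intercept may be `-Inf` for the degenerate no-nuisance
#' variant of the trinomial model (the `1*` state has zero mass).
#'
#' @param kind `"binary_with_contamination"` or `"trinomial"`.
#' @param B Numeric vector `(beta0, betaG, betaX, betaGxX)` in log-odds units.
#' @param B_star Coefficients of the nuisance state (trinomial only).
#' @param Z_effects Effects of the non-interacting covariates (length must
#'   match the covariate distribution used with the model).
#' @param Z_effects_star Per-state Z effects for the nuisance state; defaults
#'   to `Z_effects` (shared main effects).
#' @param contamination A [contamination_spec()] (binary model only).
#' @return An object of class `gxe_model`.
#' @examples
#' disease_model("binary_with_contamination",
#'               B = c(-1, -0.41, log(8), 0), Z_effects = c(0, -0.08),
#'               contamination = contamination_spec(0.36, 0.06))
#' @export
disease_model <- function(kind = c("binary_with_contamination", "trinomial"),
                          B, B_star = NULL, Z_effects = numeric(),
                          Z_effects_star = NULL, contamination = NULL) {
  kind <- match.arg(kind)
  B <- named_coefs(check_coef(B, "B"), "B")
  Z_effects <- check_coef(Z_effects, "Z_effects")
  if (kind == "trinomial") {
    if (is.null(B_star)) stop("trinomial model requires `B_star`",
                              call. = FALSE)
    if (!is.null(contamination)) {
      stop("trinomial model induces its own contamination; do not supply ",
           "`contamination`", call. = FALSE)
    }
    B_star <- named_coefs(check_coef(B_star, "B_star",
                                     allow_minf_intercept = TRUE), "B_star")
    names(B_star) <- paste0(COEF_NAMES, "_star")
    if (is.null(Z_effects_star)) Z_effects_star <- Z_effects
    Z_effects_star <- check_coef(Z_effects_star, "Z_effects_star")
    if (length(Z_effects_star) != length(Z_effects)) {
      stop("`Z_effects_star` must match `Z_effects` in length", call. = FALSE)
    }
  } else {
    if (!is.null(B_star)) stop("binary model must not have `B_star`",
                               call. = FALSE)
    if (is.null(contamination)) {
      stop("binary model requires a `contamination` spec", call. = FALSE)
    }
    stopifnot(inherits(contamination, "gxe_contamination"))
    Z_effects_star <- NULL
  }
  structure(list(kind = kind, B = B, B_star = B_star,
                 Z_effects = as.numeric(Z_effects),
                 Z_effects_star = Z_effects_star,
                 contamination = contamination),
            class = "gxe_model")
}

#' Case-control study design
#'
#' @param n_controls,n_cases Numbers of clinical controls and cases sampled.
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Base seed; per-replicate generator states are derived from
#'   `(seed, replicate_index)`.
#' @return An object of class `gxe_design`.
#' @export
study_design <- function(n_controls, n_cases, replicates = 500L, seed = 1L) {
  if (n_controls < 1 || n_cases < 1 || replicates < 1) {
    stop("n_controls, n_cases and replicates must be >= 1", call. = FALSE)
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "gxe_design")
}

#' Clinical-model coefficient vector
#'
#' Coefficients of the (possibly misspecified) logistic model for the clinical
#' diagnosis, `gamma0 + gammaG g + gammaX x + gammaGxX g x (+ gammaZ z)`, with
#' a record of where they came from.
#'
#' @param gamma0,gammaG,gammaX,gammaGxX Coefficients on the log-odds scale.
#' @param gammaZ Named or unnamed vector of covariate coefficients.
#' @param provenance One of `"linearized"`, `"theoretical"`, `"oracle"`,
#'   `"mle"`.
#' @return A named numeric vector of class `gxe_gamma` with attribute
#'   `provenance`.
#' @export
gamma_vector <- function(gamma0, gammaG, gammaX, gammaGxX,
                         gammaZ = numeric(),
                         provenance = c("linearized", "theoretical",
                                        "oracle", "mle")) {
  provenance <- match.arg(provenance)
  g <- c(gamma0, gammaG, gammaX, gammaGxX, as.numeric(gammaZ))
  nz <- if (length(gammaZ)) paste0("gammaZ", seq_along(gammaZ)) else character()
  names(g) <- c(GAMMA_NAMES, nz)
  if (any(!is.finite(g))) stop("gamma coefficients must be finite",
                               call. = FALSE)
  structure(g, class = "gxe_gamma", provenance = provenance)
}

#' @export
print.gxe_gamma <- function(x, ...) {
  cat("<gxe_gamma> provenance:", attr(x, "provenance"), "\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' @export
print.gxe_model <- function(x, ...) {
  cat("<gxe_model>", x$kind, "\n  B      :",
      paste(sprintf("%s=%.4g", COEF_NAMES, x$B), collapse = ", "), "\n")
  if (!is.null(x$B_star)) {
    cat("  B_star :", paste(sprintf("%.4g", x$B_star), collapse = ", "), "\n")
  }
  if (length(x$Z_effects)) {
    cat("  Z      :", paste(sprintf("%.4g", x$Z_effects), collapse = ", "),
        "\n")
  }
  if (!is.null(x$contamination)) {
    cat(sprintf("  S(0)=%.3g, S(1)=%.3g\n",
                x$contamination$S0, x$contamination$S1))
  }
  invisible(x)
}

# Linear predictor over enumerated cells for a coefficient set.
linear_predictor <- function(cells, b, zeff) {
  eta <- b[1] + b[2] * cells$g + b[3] * cells$x + b[4] * cells$g * cells$x
  for (k in seq_along(zeff)) eta <- eta + zeff[k] * cells[[paste0("z", k)]]
  eta
}

check_model_cov <- function(model, cov) {
  if (length(model$Z_effects) != n_covariates(cov)) {
    stop("number of Z effects (", length(model$Z_effects),
         ") does not match the covariate distribution (",
         n_covariates(cov), ")", call. = FALSE)
  }
}

#' Per-cell probabilities of the true and clinical disease states
#'
#' Computes, for every covariate cell, the probabilities of the three true
#' states (`0` healthy, `1` disease of interest, `1*` nuisance) and of the
#' clinical diagnosis.  For the trinomial model the true-state probabilities
#' follow the multinomial logit directly and `DCL = 1` iff `D` is `1` or
#' `1*`.  For the binary model with contamination, the clinical-case
#' probability is `p1 / (1 - S(x))` (perfect sensitivity with per-cell
#' calibrated false positives); the contaminated clinical cases are reported
#' in the `p_d1star` column so that in both settings `DCL = 1` corresponds to
#' `D` in `{1, 1*}` and controls are clean.
#'
#' @param model A [disease_model()].
#' @param cov A [covariate_distribution()] consistent with `model`.
#' @return Data frame with the cell columns of [enumerate_cells()] plus
#'   `p_d0`, `p_d1`, `p_d1star` (sum to 1 per row) and `p_dcl1`.
#' @examples
#' m <- disease_model("trinomial", B = c(-1, -0.69, 1.3, 1.099),
#'                    B_star = c(-1.7, 0, 0.5, 0))
#' cp <- cell_probabilities(m, covariate_distribution(genotype_model(0.1), 0.14))
#' @export
cell_probabilities <- function(model, cov) {
  stopifnot(inherits(model, "gxe_model"), inherits(cov, "gxe_covariates"))
  check_model_cov(model, cov)
  cells <- enumerate_cells(cov)
  eta <- linear_predictor(cells, model$B, model$Z_effects)
  if (model$kind == "trinomial") {
    etas <- linear_predictor(cells, model$B_star, model$Z_effects_star)
    # guard overflow: divide through by the max exponent
    m <- pmax(0, eta, etas)
    e0 <- exp(-m); e1 <- exp(eta - m); es <- exp(etas - m)
    den <- e0 + e1 + es
    cells$p_d0 <- e0 / den
    cells$p_d1 <- e1 / den
    cells$p_d1star <- es / den
  } else {
    S <- ifelse(cells$x == 1, model$contamination$S1, model$contamination$S0)
    p1 <- plogis(eta)
    pcl <- p1 / (1 - S)
    bad <- pcl > 1 + 1e-12
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "infeasible contamination: pr(D=1|cell) = %.4f > 1 - S(x) = %.4f in cell (%s)",
        p1[i], 1 - S[i],
        paste(sprintf("%s=%d", setdiff(names(cells), "mass"),
                      unlist(cells[i, setdiff(names(cells), "mass")])),
              collapse = ", ")), call. = FALSE)
    }
    pcl <- pmin(pcl, 1)
    cells$p_d1 <- p1
    cells$p_d1star <- pcl - p1          # contaminated clinical cases
    cells$p_d0 <- 1 - pcl               # undiagnosed (all truly D != 1)
  }
  cells$p_dcl1 <- cells$p_d1 + cells$p_d1star
  cells
}

#' Population rates induced by a risk model
#'
#' Marginalizes [cell_probabilities()] over the covariate distribution to
#' obtain the population probabilities of the clinical diagnosis
#' (`pi_dcl`) and of the true states (`pi_d`), the per-stratum state
#' probabilities, and the induced contamination rates
#' `S(x) = pr(D != 1 | DCL = 1, X = x)` with `tau(x) = 1 - S(x)`.
#'
#' @inheritParams cell_probabilities
#' @return A list of class `gxe_rates` with components `pi_dcl` (named
#'   `"0"`, `"1"`), `pi_d` (named `"0"`, `"1"`, `"1star"`), `by_stratum`
#'   (data frame, one row per value of X), `S_induced` and `tau_induced`
#'   (length-2 vectors indexed by X = 0, 1).
#' @export
derive_population_rates <- function(model, cov) {
  cp <- cell_probabilities(model, cov)
  pi1cl <- sum(cp$mass * cp$p_dcl1)
  pi_d <- c(`0` = sum(cp$mass * cp$p_d0),
            `1` = sum(cp$mass * cp$p_d1),
            `1star` = sum(cp$mass * cp$p_d1star))
  by_stratum <- do.call(rbind, lapply(0:1, function(xx) {
    i <- cp$x == xx
    w <- cp$mass[i] / sum(cp$mass[i])
    data.frame(x = xx,
               pr_d0 = sum(w * cp$p_d0[i]),
               pr_d1 = sum(w * cp$p_d1[i]),
               pr_d1star = sum(w * cp$p_d1star[i]),
               pr_dcl1 = sum(w * cp$p_dcl1[i]))
  }))
  S_ind <- with(by_stratum, ifelse(pr_dcl1 > 0, pr_d1star / pr_dcl1, NA_real_))
  names(S_ind) <- c("S0", "S1")
  structure(list(pi_dcl = c(`0` = 1 - pi1cl, `1` = pi1cl),
                 pi_d = pi_d,
                 by_stratum = by_stratum,
                 S_induced = S_ind,
                 tau_induced = 1 - S_ind),
            class = "gxe_rates")
}

#' @export
print.gxe_rates <- function(x, ...) {
  cat("<gxe_rates>\n  pr(DCL=1) =", signif(x$pi_dcl["1"], 4),
      "\n  pi_d      =", paste(signif(x$pi_d, 4), collapse = " / "),
      "\n  induced S(0) =", signif(x$S_induced[1], 4),
      " S(1) =", signif(x$S_induced[2], 4), "\n")
  invisible(x)
}
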