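# Per-SNP bias screen: apply the closed-form approximations in reverse to a
# table of fitted clinical-model coefficients, under model-1 (contamination)
# and optionally model-2 (explicit nuisance coefficients) assumptions.

required_fit_cols <- c("snp_id", "gamma0_hat", "gammaG_hat", "gammaX_hat",
                       "gammaGxX_hat", "p_G", "p_GxX")

validate_fit_table <- function(fits) {
  missing <- setdiff(required_fit_cols, names(fits))
  if (length(missing)) {
    stop("SNP fit table is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(fits$snp_id)) {
    stop("`snp_id` must be unique", call. = FALSE)
  }
  pcols <- grep("^p_", names(fits), value = TRUE)
  for (pc in pcols) {
    p <- fits[[pc]]
    if (any(!is.na(p) & (p < 0 | p > 1))) {
      stop("p-values in column ", pc, " must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(fits)
}

zcols_of_fits <- function(fits) {
  grep("^gammaZ[0-9]+_hat$", names(fits), value = TRUE)
}

#' Fit the clinical model to every SNP of a screen fixture
#'
#' Convenience wrapper producing the SNP fit table consumed by
#' [snp_screen()] from a [make_snp_screen_fixture()] object: one logistic fit
#' of `dcl` on `(G, X, GxX, Z...)` per SNP column, with Wald p-values.
#'
#' @param fixture Output of [make_snp_screen_fixture()].
#' @return Data frame with columns `snp_id`, `gamma0_hat`, `gammaG_hat`,
#'   `gammaX_hat`, `gammaGxX_hat`, `gammaZ*_hat`, `p_G`, `p_X`, `p_GxX`,
#'   `separated`.
#' @export
fit_snp_screen <- function(fixture) {
  base <- fixture$base
  zc <- grep("^z[0-9]+$", names(base), value = TRUE)
  rows <- lapply(seq_len(ncol(fixture$genotypes)), function(s) {
    dat <- cbind(data.frame(dcl = base$dcl, g = fixture$genotypes[, s],
                            x = base$x), base[zc])
    fit <- fit_clinical_logistic(dat)
    se <- attr(fit, "se")
    wald_p <- function(term) {
      z <- as.numeric(fit)[match(term_to_gamma(term), names(fit))] / se[term]
      2 * stats::pnorm(-abs(z))
    }
    out <- data.frame(snp_id = colnames(fixture$genotypes)[s],
                      gamma0_hat = fit[["gamma0"]],
                      gammaG_hat = fit[["gammaG"]],
                      gammaX_hat = fit[["gammaX"]],
                      gammaGxX_hat = fit[["gammaGxX"]])
    for (k in seq_along(zc)) {
      out[[paste0("gammaZ", k, "_hat")]] <- fit[[paste0("gammaZ", k)]]
    }
    out$p_G <- wald_p("G"); out$p_X <- wald_p("X"); out$p_GxX <- wald_p("GxX")
    out$separated <- attr(fit, "separated")
    out
  })
  do.call(rbind, rows)
}

#' Screen fitted SNP coefficients for contamination bias
#'
#' For each SNP's fitted clinical-model coefficients, computes corrected
#' coefficient estimates by inverting the linearized bias map
#' ([invert_bias()]), the implied bias `gamma_hat - corrected`, and the
#' first-order plug-in bias (linearized map evaluated at `gamma_hat`), under
#' model-1 assumptions (contamination rates) and, when nuisance-state
#' coefficients are supplied, under model-2 assumptions as well.  Coefficients
#' with p-value columns receive a Bonferroni significance flag at
#' `alpha / n_snps`.
#'
#' @param fits SNP fit table (see [fit_snp_screen()] for the schema).
#' @param contamination A [contamination_spec()]; the model-1 assumption.
#'   Defaults to the ApoE-e4-differential rates `S = (0.36, 0.06)`.
#' @param model2_assumptions Optional named list/vector with nuisance-state
#'   coefficients `beta0_star`, `betaG_star`, `betaX_star`, `betaGxX_star`
#'   (and optionally `Z_effects_star`); no defaults are invented.
#' @param alpha Familywise error target for the Bonferroni flag.
#' @param correct_terms Coefficients corrected by inversion (default the
#'   three slopes `betaG`, `betaX`, `betaGxX`).  The fitted intercept and
#'   covariate coefficients are used as plug-ins: a retrospective fit's
#'   intercept absorbs the case-control sampling ratio and must not be
#'   inverted through the prospective bias map.
#' @return Data frame of class `gxe_screen_report`: one row per SNP,
#'   assumption set (`model1`, `model2`) and coefficient, with columns
#'   `snp_id`, `assumption`, `term`, `gamma_hat`, `corrected`,
#'   `bias_corrected`, `bias_plugin`, `inversion_converged`, `p_value`,
#'   `bonferroni_threshold`, `significant`.
#' @export
snp_screen <- function(fits, contamination = contamination_spec(0.36, 0.06),
                       model2_assumptions = NULL, alpha = 0.05,
                       correct_terms = c("betaG", "betaX", "betaGxX")) {
  validate_fit_table(fits)
  if (!inherits(contamination, "gxe_contamination")) {
    contamination <- contamination_spec(contamination[1], contamination[2])
  }
  m <- nrow(fits)
  thr <- alpha / m
  zc <- zcols_of_fits(fits)
  n_z <- length(zc)
  gcols <- c("gamma0_hat", "gammaG_hat", "gammaX_hat", "gammaGxX_hat", zc)
  terms <- c(GAMMA_NAMES, if (n_z) paste0("gammaZ", seq_len(n_z)))
  pmap <- c(gammaG = "p_G", gammaX = "p_X", gammaGxX = "p_GxX")

  assumptions <- list(model1 = function(gh) {
    invert_bias(gh, "model1", S = contamination, n_z = n_z,
                solve_for = correct_terms)
  })
  if (!is.null(model2_assumptions)) {
    a <- as.list(model2_assumptions)
    need <- c("beta0_star", "betaG_star", "betaX_star", "betaGxX_star")
    if (!all(need %in% names(a))) {
      stop("model2 assumptions must name: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    Bs <- as.numeric(a[need])
    Zs <- if (!is.null(a$Z_effects_star)) as.numeric(a$Z_effects_star) else
      rep(0, n_z)
    assumptions$model2 <- function(gh) {
      invert_bias(gh, "model2", B_star = Bs, Z_effects_star = Zs, n_z = n_z,
                  solve_for = correct_terms)
    }
  }

  rows <- list()
  for (i in seq_len(m)) {
    gh <- as.numeric(fits[i, gcols])
    for (an in names(assumptions)) {
      inv <- tryCatch(assumptions[[an]](gh), error = function(e) NULL)
      corrected <- if (is.null(inv)) rep(NA_real_, length(gh)) else
        as.numeric(inv$corrected)
      plug <- if (is.null(inv)) {
        tryCatch({
          if (an == "model1") {
            as.numeric(approx_gamma_model1(
              gh[1:4], contamination,
              Z_effects = gh[seq_len(n_z) + 4])$linearized) - gh
          } else {
            as.numeric(approx_gamma_model2(
              gh[1:4], Bs, Z_effects = gh[seq_len(n_z) + 4],
              Z_effects_star = Zs)$linearized) - gh
          }
        }, error = function(e) rep(NA_real_, length(gh)))
      } else as.numeric(inv$plug_in_bias)
      pv <- rep(NA_real_, length(terms))
      for (tm in names(pmap)) {
        if (pmap[[tm]] %in% names(fits)) {
          pv[terms == tm] <- fits[[pmap[[tm]]]][i]
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = fits$snp_id[i], assumption = an, term = terms,
        gamma_hat = gh, corrected = corrected,
        bias_corrected = gh - corrected,
        bias_plugin = plug,
        inversion_converged = !is.null(inv),
        p_value = pv, bonferroni_threshold = thr,
        significant = !is.na(pv) & pv < thr, row.names = NULL)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "n_snps") <- m
  attr(res, "alpha") <- alpha
  class(res) <- c("gxe_screen_report", class(res))
  res
}
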