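test_that("binary-model approximations match independent hand evaluation", {
  a <- approx_gamma_model1(B = c(-1, -0.41, 2.1, 0), S = c(0.36, 0.06))
  # gammaG: attenuation weight e^b0 / (e^b0 + S0)
  expect_equal(a$linearized[["gammaG"]],
               exp(-1) / (exp(-1) + 0.36) * (-0.41), tolerance = 1e-12)
  expect_equal(round(a$linearized[["gammaG"]], 4), -0.2072)
  # gamma0: log{(1+S0)/(1-S0)} + b0/(1+S0)
  expect_equal(a$linearized[["gamma0"]], log(1.36 / 0.64) - 1 / 1.36,
               tolerance = 1e-12)
  expect_equal(round(a$linearized[["gamma0"]], 4), 0.0185)
  # theoretical contrasts of log{(S + e^eta)/(1-S)}
  expect_equal(a$theoretical[["gammaX"]],
               log((0.06 + exp(-1 + 2.1)) / 0.94) -
                 log((0.36 + exp(-1)) / 0.64), tolerance = 1e-12)
  expect_equal(a$theoretical[["gammaG"]],
               log(0.36 + exp(-1.41)) - log(0.36 + exp(-1)),
               tolerance = 1e-12)
})

test_that("trinomial approximations match independent hand evaluation", {
  b <- approx_gamma_model2(B = c(-1, -0.69, 1.3, 1.099),
                           B_star = c(-1.7, 0, 0.5, 0))
  expect_equal(b$theoretical[["gammaX"]],
               log(exp(0.3) + exp(-1.2)) - log(exp(-1) + exp(-1.7)),
               tolerance = 1e-12)
  expect_equal(round(b$theoretical[["gammaX"]], 3), 1.098)
  expect_equal(b$linearized[["gammaG"]],
               exp(-1) / (exp(-1) + exp(-1.7)) * (-0.69), tolerance = 1e-12)
  expect_equal(round(b$linearized[["gammaG"]], 3), -0.461)
  # degenerate no-nuisance model collapses both forms to B
  clean <- approx_gamma_model2(B = c(-1, 0.4, -0.2, 0.7),
                               B_star = c(-Inf, 0, 0, 0))
  expect_equal(as.numeric(clean$theoretical), c(-1, 0.4, -0.2, 0.7))
  expect_equal(as.numeric(clean$linearized), c(-1, 0.4, -0.2, 0.7))
})

test_that("no contamination means no bias, for all coefficients and forms", {
  set.seed(11)
  for (r in 1:50) {
    B <- rand_B()
    zeff <- runif(2, -1, 1)
    a <- approx_gamma_model1(B, c(0, 0), Z_effects = zeff)
    expect_equal(as.numeric(a$theoretical), c(B, zeff), tolerance = 1e-12)
    expect_equal(as.numeric(a$linearized), c(B, zeff), tolerance = 1e-12)
  }
})

test_that("remarks hold as predicates and cautionary flags fire", {
  df1 <- remarks_predicates("model1", B = c(-1, 0.8, 1.2, 0.4),
                            B_star_or_S = c(0.36, 0.06))
  expect_true(all(df1$holds[df1$universal]))
  # differential contamination biases a null X effect (cautionary row)
  expect_true(df1$holds[df1$remark_id == "m1_null_X_may_bias"])
  # nondifferential contamination: the same flag must NOT fire
  df1n <- remarks_predicates("model1", B = c(-1, 0.8, 1.2, 0),
                             B_star_or_S = c(0.2, 0.2))
  expect_false(df1n$holds[df1n$remark_id == "m1_null_X_may_bias"])
  df2 <- remarks_predicates("model2", B = c(-1, -0.69, 1.3, 1.099),
                            B_star_or_S = c(-1.7, 0, 0.5, 0))
  expect_true(all(df2$holds[df2$universal]))
})

test_that("linearized converges to theoretical as the own coefficient shrinks", {
  S <- contamination_spec(0.36, 0.06)
  Bs <- c(-1.7, 0.2, 0.5, -0.3)
  for (coef in c("betaG", "betaX", "betaGxX")) {
    gaps1 <- gaps2 <- numeric()
    for (b in c(1, 0.5, 0.25, 0.125, 0.0625)) {
      B <- c(beta0 = -1, betaG = 0.4, betaX = 0.6, betaGxX = 0.2)
      B[coef] <- b
      gname <- sub("beta", "gamma", coef)
      a <- approx_gamma_model1(B, S)
      gaps1 <- c(gaps1, abs(a$linearized[[gname]] - a$theoretical[[gname]]))
      m2 <- approx_gamma_model2(B, Bs)
      gaps2 <- c(gaps2, abs(m2$linearized[[gname]] - m2$theoretical[[gname]]))
    }
    expect_true(all(diff(gaps1) < 0))
    expect_true(all(diff(gaps2) < 0))
  }
  # model-1 intercept converges too (model-2 gamma0 is excluded: its printed
  # linearization does not approach the log-form as beta0 -> 0)
  gaps0 <- sapply(c(1, 0.5, 0.25, 0.125), function(b) {
    a <- approx_gamma_model1(c(b, 0.4, 0.6, 0.2), S)
    abs(a$linearized[["gamma0"]] - a$theoretical[["gamma0"]])
  })
  expect_true(all(diff(gaps0) < 0))
})

test_that("trinomial theoretical slopes equal the oracle in the saturated case", {
  set.seed(23)
  for (r in 1:10) {
    cov <- rand_cov()
    m <- rand_trinomial(scale = 1.5)
    th <- approx_gamma_model2(m$B, m$B_star)$theoretical
    g <- pseudo_true_gamma(pseudo_true_problem(m, cov, 0.5))
    expect_equal(as.numeric(g)[2:4], as.numeric(th)[2:4], tolerance = 1e-8)
  }
})

test_that("Z-extension weights are exact for shared Z effects", {
  # shared Z effects keep the clinical model correctly specified in Z, so
  # gammaZ = betaZ exactly in both the formulas and the oracle
  m <- setting_b_model()
  apx <- approx_gamma(m)
  expect_equal(as.numeric(apx$theoretical)[5:6], c(0.10, -0.083),
               tolerance = 1e-12)
  g <- pseudo_true_gamma(pseudo_true_problem(m, cov_gxz(), 0.5))
  expect_equal(as.numeric(g)[5:6], c(0.10, -0.083), tolerance = 1e-8)
})

test_that("invert_bias round-trips the linearized map", {
  set.seed(31)
  for (r in 1:20) {
    B <- runif(4, -1, 1)
    gh1 <- approx_gamma_model1(B, c(0.36, 0.06))$linearized
    out1 <- invert_bias(gh1, "model1", S = c(0.36, 0.06))
    expect_true(out1$converged)
    expect_lt(max(abs(out1$corrected - B)), 1e-6)

    Bs <- runif(4, -2, 0)
    gh2 <- approx_gamma_model2(B, Bs)$linearized
    out2 <- invert_bias(gh2, "model2", B_star = Bs)
    expect_lt(max(abs(out2$corrected - B)), 1e-6)
  }
})

test_that("invert_bias with zero contamination is the identity", {
  gh <- gamma_vector(-0.5, 0.3, 1.1, -0.2, provenance = "mle")
  out <- invert_bias(gh, "model1", S = c(0, 0))
  expect_equal(unname(out$corrected), as.numeric(gh), tolerance = 1e-10)
  expect_equal(unname(out$plug_in_bias), rep(0, 4), tolerance = 1e-12)
})

test_that("invert_bias honors solve_for subsets", {
  B <- c(-1, 0.6, 1.2, 0.3)
  gh <- approx_gamma_model1(B, c(0.36, 0.06))$linearized
  out <- invert_bias(gh, "model1", S = c(0.36, 0.06),
                     solve_for = c("betaG", "betaX", "betaGxX"))
  # intercept stays at its gamma_hat plug-in value
  expect_equal(out$corrected[["beta0"]], gh[["gamma0"]])
  expect_setequal(out$solved_for, c("betaG", "betaX", "betaGxX"))
  expect_lt(out$residual, 1e-10)
})

test_that("unphysical coefficients are rejected", {
  expect_error(approx_gamma_model1(c(25, 0, 0, 0), c(0.1, 0.1)),
               "unphysical")
  expect_error(contamination_spec(0.5, 1), "\\[0, 1\\)")
})
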