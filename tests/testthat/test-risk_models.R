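test_that("hwe_probabilities matches the closed form and validates input", {
  expect_equal(hwe_probabilities(0.5), c(AA = 0.25, Aa = 0.5, aa = 0.25))
  expect_equal(hwe_probabilities(0), c(AA = 1, Aa = 0, aa = 0))
  expect_equal(hwe_probabilities(0.1), c(AA = 0.81, Aa = 0.18, aa = 0.01))
  for (th in seq(0, 1, by = 0.05)) {
    p <- hwe_probabilities(th)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1)
  }
  expect_error(hwe_probabilities(1.2), "0, 1")
  expect_error(hwe_probabilities(-0.1), "0, 1")
})

test_that("genotype codings give the documented indicator frequencies", {
  th <- 0.3
  expect_equal(genotype_freq(genotype_model(th, "raw_bernoulli")), th)
  expect_equal(genotype_freq(genotype_model(th, "dominant_carrier")),
               1 - (1 - th)^2)
  expect_equal(genotype_freq(genotype_model(th, "recessive")), th^2)
})

test_that("enumerate_cells has 2^(2+K) cells with masses summing to 1", {
  for (K in 0:3) {
    cov <- covariate_distribution(genotype_model(0.2), 0.3,
                                  covariate_freqs = rep(0.4, K))
    cells <- enumerate_cells(cov)
    expect_equal(nrow(cells), 2^(2 + K))
    expect_equal(sum(cells$mass), 1)
  }
})

test_that("trinomial cell probabilities follow the multinomial logit", {
  # all coefficients zero: symmetric multinomial
  m0 <- disease_model("trinomial", B = rep(0, 4), B_star = rep(0, 4))
  cp0 <- cell_probabilities(m0, cov_gx())
  expect_equal(cp0$p_d0, rep(1 / 3, 4))
  expect_equal(cp0$p_d1, rep(1 / 3, 4))
  expect_equal(cp0$p_d1star, rep(1 / 3, 4))

  # hand evaluation at the frozen trinomial parameters, cell (g=0, x=1):
  # eta = -1 + 1.3 = 0.3, eta* = -1.7 + 0.5 = -1.2
  cp <- cell_probabilities(setting_b_model(n_z = 0), cov_gx())
  i <- which(cp$g == 0 & cp$x == 1)
  expect_equal(cp$p_d1[i], exp(0.3) / (1 + exp(0.3) + exp(-1.2)),
               tolerance = 1e-12)
  expect_equal(round(cp$p_d1[i], 4), 0.5092)

  # rows normalize for random models
  set.seed(41)
  for (r in 1:20) {
    cov <- rand_cov(n_z = sample(0:2, 1))
    m <- rand_trinomial(n_z = n_covariates(cov))
    cp <- cell_probabilities(m, cov)
    expect_equal(cp$p_d0 + cp$p_d1 + cp$p_d1star, rep(1, nrow(cp)),
                 tolerance = 1e-12)
    expect_true(all(cp$p_dcl1 >= 0 & cp$p_dcl1 <= 1))
  }
})

test_that("binary-with-contamination clinical law is p1/(1-S) and guards feasibility", {
  # S = 0: clinical and true probabilities coincide exactly
  m0 <- disease_model("binary_with_contamination", B = c(-1, 0.5, 1, -0.3),
                      contamination = contamination_spec(0, 0))
  cp0 <- cell_probabilities(m0, cov_gx())
  eta <- -1 + 0.5 * cp0$g + 1 * cp0$x - 0.3 * cp0$g * cp0$x
  expect_equal(cp0$p_dcl1, plogis(eta))
  expect_equal(cp0$p_d1star, rep(0, 4))

  # the contaminated fraction of clinical cases is S(x) in every cell
  m <- setting_a_model()
  cp <- cell_probabilities(m, cov_gxz())
  S <- ifelse(cp$x == 1, 0.06, 0.36)
  expect_equal(cp$p_d1star / cp$p_dcl1, S, tolerance = 1e-12)

  # infeasible cell is named
  m_bad <- disease_model("binary_with_contamination", B = c(2, 0, 2, 0),
                         contamination = contamination_spec(0.1, 0.5))
  expect_error(cell_probabilities(m_bad, cov_gx()),
               "infeasible contamination.*x=1")
})

test_that("derive_population_rates recovers specified and induced rates", {
  # binary model: induced S equals the specification to numerical precision
  r <- derive_population_rates(setting_a_model(), cov_gxz())
  expect_equal(unname(r$S_induced), c(0.36, 0.06), tolerance = 1e-12)
  expect_equal(unname(r$tau_induced), c(0.64, 0.94), tolerance = 1e-12)
  expect_equal(sum(r$pi_d), 1, tolerance = 1e-12)

  # exchangeable disease states: B = B* gives pi_1 = pi_1*
  m_sym <- disease_model("trinomial", B = c(-1, 0.3, 0.7, 0.1),
                         B_star = c(-1, 0.3, 0.7, 0.1))
  r_sym <- derive_population_rates(m_sym, cov_gx())
  expect_equal(r_sym$pi_d[["1"]], r_sym$pi_d[["1star"]], tolerance = 1e-12)
})

test_that("population rates agree with naive per-subject Monte-Carlo at n = 1e6", {
  set.seed(99)
  cov <- rand_cov(n_z = 1)
  m <- rand_trinomial(scale = 1.5, n_z = 1)
  cp <- cell_probabilities(m, cov)
  n <- 1e6
  # naive simulation: draw a cell, then the true state within the cell
  cell_idx <- sample.int(nrow(cp), n, replace = TRUE, prob = cp$mass)
  u <- runif(n)
  p1 <- cp$p_d1[cell_idx]; ps <- cp$p_d1star[cell_idx]
  dcl <- as.integer(u < p1 + ps)
  pi1_hat <- mean(dcl)
  r <- derive_population_rates(m, cov)
  se <- sqrt(pi1_hat * (1 - pi1_hat) / n)
  expect_lt(abs(pi1_hat - r$pi_dcl[["1"]]), 3 * se)
  # per-stratum contamination
  x <- cp$x[cell_idx]
  for (xx in 0:1) {
    sel <- dcl == 1 & x == xx
    S_hat <- mean(u[sel] >= p1[sel])  # nuisance among clinical cases
    se_s <- sqrt(S_hat * (1 - S_hat) / sum(sel))
    expect_lt(abs(S_hat - r$S_induced[xx + 1]), 3 * se_s + 1e-12)
  }
})

test_that("recoding X -> 1-X leaves cell probabilities invariant", {
  flip <- function(b) c(b[1] + b[3], b[2] + b[4], -b[3], -b[4])
  set.seed(7)
  for (r in 1:20) {
    cov <- rand_cov()
    cov_f <- covariate_distribution(cov$genotype, 1 - cov$env_freq)
    m <- rand_trinomial(scale = 1.5)
    m_f <- disease_model("trinomial", B = flip(m$B), B_star = flip(m$B_star))
    cp <- cell_probabilities(m, cov)
    cp_f <- cell_probabilities(m_f, cov_f)
    # match cells after x -> 1 - x
    key <- paste(cp$g, cp$x); key_f <- paste(cp_f$g, 1 - cp_f$x)
    j <- match(key, key_f)
    for (col in c("mass", "p_d0", "p_d1", "p_d1star", "p_dcl1")) {
      expect_equal(cp[[col]], cp_f[[col]][j], tolerance = 1e-12)
    }
  }
})
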