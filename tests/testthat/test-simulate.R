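test_that("simulation is deterministic and respects the design counts", {
  m <- setting_b_model()
  cov <- cov_gxz()
  des <- study_design(150, 250, replicates = 3, seed = 42)
  d1 <- simulate_dataset(m, cov, des, replicate_index = 2)
  d2 <- simulate_dataset(m, cov, des, replicate_index = 2)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(m, cov, des, replicate_index = 3)
  expect_false(identical(d1$g, d3$g))

  expect_equal(sum(d1$dcl == 1), 250)
  expect_equal(sum(d1$dcl == 0), 150)
  # controls are clean; clinical cases are one of the two disease states
  expect_true(all(d1$d_true[d1$dcl == 0] == 0))
  expect_true(all(d1$d_true[d1$dcl == 1] %in% c(1, 2)))
  expect_error(simulate_dataset(m, cov, des, replicate_index = 4),
               "replicate_index")
})

test_that("contamination fractions among clinical cases match the stated rates", {
  # binary mechanism: pr(d_true != 1 | dcl = 1, x) = S(x) per stratum
  d <- simulate_dataset(setting_a_model(), cov_gxz(),
                        study_design(3000, 3000, seed = 5))
  cases <- d[d$dcl == 1, ]
  for (xx in 0:1) {
    sel <- cases$x == xx
    k <- sum(cases$d_true[sel] == 2)
    n <- sum(sel)
    S_true <- if (xx == 1) 0.06 else 0.36
    # 99% binomial bounds
    bounds <- qbinom(c(0.005, 0.995), n, S_true)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
})

test_that("trinomial nuisance fraction matches the induced rate", {
  m <- setting_b_model()
  cov <- cov_gxz()
  r <- derive_population_rates(m, cov)
  d <- simulate_dataset(m, cov, study_design(1000, 3000, seed = 8))
  cases <- d[d$dcl == 1, ]
  for (xx in 0:1) {
    sel <- cases$x == xx
    k <- sum(cases$d_true[sel] == 2)
    bounds <- qbinom(c(0.005, 0.995), sum(sel), r$S_induced[xx + 1])
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
})

test_that("contaminant fraction is independent of genotype (per-cell calibration)", {
  d <- simulate_dataset(setting_a_model(), cov_gxz(),
                        study_design(2000, 20000, seed = 13))
  cases <- d[d$dcl == 1 & d$x == 0, ]
  p_by_g <- tapply(cases$d_true == 2, cases$g, mean)
  n_by_g <- table(cases$g)
  se <- sqrt(0.36 * 0.64 * sum(1 / n_by_g))
  expect_lt(abs(p_by_g[["1"]] - p_by_g[["0"]]), 3 * se)
})

test_that("control covariates follow pr(cell | dcl = 0) across 50 seeds", {
  m <- setting_b_model()
  cov <- cov_gxz()
  cp <- cell_probabilities(m, cov)
  p_cells <- cp$mass * (1 - cp$p_dcl1) / sum(cp$mass * (1 - cp$p_dcl1))
  key_cells <- paste(cp$g, cp$x, cp$z1, cp$z2)
  pvals <- sapply(1:50, function(s) {
    d <- simulate_dataset(m, cov, study_design(2000, 50, seed = 1000 + s))
    ctrl <- d[d$dcl == 0, ]
    obs <- table(factor(paste(ctrl$g, ctrl$x, ctrl$z1, ctrl$z2),
                        levels = key_cells))
    expected <- 2000 * p_cells
    stat <- sum((obs - expected)^2 / expected)
    pchisq(stat, df = length(p_cells) - 1, lower.tail = FALSE)
  })
  # Under a correct sampler the 50 goodness-of-fit p-values are uniform; a
  # literal "each p > 0.001" check falsely fails ~5% of seed blocks, so the
  # calibrated aggregate check is used at the same alpha.
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
  expect_gt(min(pvals), 1e-5)
})

test_that("snp screen fixture bookkeeping and determinism", {
  cov <- cov_gxz()
  des <- study_design(300, 300, seed = 77)
  fx <- make_snp_screen_fixture(133, cov, des)
  expect_equal(nrow(fx$truth), 133)
  expect_true(all(fx$truth$betaG == 0) && all(fx$truth$betaGxX == 0))
  expect_equal(ncol(fx$genotypes), 133)
  expect_equal(nrow(fx$base), 600)

  fx5 <- make_snp_screen_fixture(10, cov, des,
                                 effect_spec = list(n_nonnull = 5,
                                                    betaG = 0.7,
                                                    betaGxX = 0.2))
  expect_equal(sum(fx5$truth$nonnull), 5)
  expect_equal(sum(fx5$truth$betaG != 0), 5)

  fx5b <- make_snp_screen_fixture(10, cov, des,
                                  effect_spec = list(n_nonnull = 5,
                                                     betaG = 0.7,
                                                     betaGxX = 0.2))
  expect_identical(fx5$truth, fx5b$truth)
  expect_identical(fx5$genotypes, fx5b$genotypes)
})

test_that("datasets round-trip through CSV with sidecar metadata", {
  d <- simulate_dataset(setting_b_model(), cov_gxz(),
                        study_design(50, 50, seed = 3))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".meta.json"))), add = TRUE)
  write_dataset(d, path)
  back <- utils::read.csv(path)
  expect_equal(back, as.data.frame(d), ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 3)
  expect_equal(meta$d_true_coding$`2`, "nuisance state (1*)")
})
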