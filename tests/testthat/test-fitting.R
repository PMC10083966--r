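test_that("step 1 recovers the free-anion product from pH-7 records", {
  recs <- simulate_mobilities(gt, design_grid(replicates = 1L), no_noise, seed = 1)
  s1 <- fit_step1(recs)
  # the pH-7 plateau carries a small residual-protonation bias for the
  # weaker acid (pKa 4.5): 1/(1 + 10^(pKa-7)) of the free product
  for (a in c("R", "C")) {
    est <- s1$eta_mu[s1$analyte == a] * 1e-11
    shortfall <- 1 / (1 + 10^(gt[[a]]$pKa$pK0 - 7))
    expect_equal(est, gt[[a]]$eta_mu_free * shortfall, tolerance = 1e-3)
    expect_equal(est, gt[[a]]$eta_mu_free, tolerance = 5e-3)
  }
  # the eta-mu product is nearly temperature-independent across T; the
  # residual spread comes from pKa(T) moving the tiny protonated fraction
  expect_lt(s1$sd[1] / s1$eta_mu[1], 1e-3)
  expect_error(fit_step1(recs[recs$pH < 7, ]), "no pH-7")
})

test_that("step-1 noisy estimates land within three standard errors", {
  set.seed(5)
  recs <- simulate_mobilities(gt, design_grid(), noise_model(), seed = 6)
  s1 <- fit_step1(recs)
  for (a in c("R", "C")) {
    row <- s1[s1$analyte == a, ]
    expect_lt(abs(row$eta_mu * 1e-11 - gt[[a]]$eta_mu_free),
              3 * row$se * 1e-11 + 0.004 * gt[[a]]$eta_mu_free)
  }
})

test_that("step 2 matches the two-point algebraic inversion oracle", {
  emf <- 2.056
  K_true <- 10^2.16
  emc_true <- 1.13
  cc <- c(0.005, 0.015)
  y <- (emf + K_true * cc * emc_true) / (1 + K_true * cc)
  oracle <- two_point_isotherm(cc[1], y[1], cc[2], y[2], emf)
  expect_equal(oracle$K, K_true, tolerance = 1e-9)
  d <- data.frame(cCD = cc, cmCD = 0, theta = 26, pH = 7,
                  mobility = y * 1e-11 / buffer_viscosity(viscosity_model(), cc, 26))
  f <- fit_step2(d, emf, "CD")
  expect_equal(10^(-f$pK_anion), oracle$K, tolerance = 1e-6)
  expect_equal(f$eta_mu_complex, oracle$eta_mu_complex, tolerance = 1e-6)
})

test_that("step 2 recovers the binding constant from a noise-free grid", {
  emf <- 2.056
  cc <- c(0, 0.0025, 0.005, 0.0075, 0.0125, 0.015)
  K <- 10^2.16
  y <- (emf + K * cc * 1.13) / (1 + K * cc)
  d <- data.frame(cCD = cc, cmCD = 0, theta = 26, pH = 7,
                  mobility = y * 1e-11 / buffer_viscosity(viscosity_model(), cc, 26))
  f <- fit_step2(d, emf, "CD")
  expect_equal(f$pK_anion, -2.16, tolerance = 1e-6)
  expect_true(f$converged)
  expect_error(fit_step2(d[1:2, ], emf, "CD"), "2 distinct positive")
})

test_that("step-2 one-sigma intervals have roughly nominal coverage", {
  set.seed(7)
  emf <- 2.056
  cc <- rep(c(0.0025, 0.005, 0.0075, 0.015), each = 3)
  K <- 10^2.16
  truth_y <- (emf + K * cc * 1.13) / (1 + K * cc)
  hits <- replicate(100, {
    y <- truth_y * (1 + 0.01 * rnorm(length(cc)))
    d <- data.frame(cCD = cc, cmCD = 0, theta = 26, pH = 7,
                    mobility = y * 1e-11 / buffer_viscosity(viscosity_model(), cc, 26))
    f <- fit_step2(d, emf, "CD")
    abs(f$pK_anion + 2.16) <= f$se_pK_anion
  })
  expect_gte(mean(hits), 0.58)
  expect_lte(mean(hits), 0.78)
})

test_that("step 3 recovers the apparent pKa and inverts to K_neutral", {
  emx7 <- 1.8
  pka_app <- 5.341
  ph <- c(2.9, 3.4, 4.0, 4.6, 5.2, 7.0)
  y <- emx7 / (1 + 10^(pka_app - ph))
  d <- data.frame(pH = ph, cCD = 0, cmCD = 0, theta = 26,
                  mobility = y * 1e-11 / buffer_viscosity(viscosity_model(), 0, 26))
  f <- fit_step3(d, emx7)
  expect_equal(f$pKa_app, pka_app, tolerance = 1e-9)
  expect_error(fit_step3(d[1:3, ], emx7), "4 distinct")
  # algebraic inversion of the shift to the neutral binding constant
  dpk <- 0.797
  Kh <- (10^dpk * (1 + 143.5 * 0.015) - 1) / 0.015
  expect_equal(Kh, 1250, tolerance = 2e-3)
  expect_equal(log10(Kh), 3.097, tolerance = 1e-3)
})

test_that("pK linearization is exact on exact lines and weighting helps", {
  th <- c(15, 20, 26, 31, 37)
  pk <- -2.157 + 0.0082 * (th - 26)
  p <- linearize_pk(pk, th)
  expect_equal(p$pK0, -2.157, tolerance = 1e-9)
  expect_equal(p$lam, 0.0082, tolerance = 1e-9)
  expect_error(linearize_pk(pk[1:2], th[1:2]), ">= 3")
  # heteroscedastic noise: inverse-variance weighting beats unweighted
  set.seed(8)
  se <- c(0.1, 0.1, 0.01, 0.01, 0.01)
  err <- replicate(200, {
    noisy <- pk + rnorm(5, sd = se)
    w <- linearize_pk(noisy, th, se)
    u <- linearize_pk(noisy, th)
    c(w$pK0 + 2.157, u$pK0 + 2.157)
  })
  expect_lt(sqrt(mean(err[1, ]^2)), sqrt(mean(err[2, ]^2)))
})

test_that("the stepwise pipeline reports the expected audit counts", {
  recs <- simulate_mobilities(gt, design_grid(replicates = 1L), no_noise, seed = 2)
  sw <- fit_stepwise(recs)
  expect_identical(sw$audit$n_fits, 52L)
  expect_identical(sw$audit$n_parameters, 72L)
  # near-recovery of the generating constants (small plateau bias aside)
  lin <- sw$linear
  expect_equal(lin$pK0[lin$analyte == "R" & lin$equilibrium == "acid"],
               2.997, tolerance = 1e-3)
  expect_equal(lin$pK0[lin$analyte == "C" & lin$equilibrium == "anion_mCD"],
               -2.157, tolerance = 0.01)
  expect_equal(lin$lam[lin$analyte == "R" & lin$equilibrium == "neutral_mCD"],
               0.017, tolerance = 0.01)
})

test_that("the global fit recovers all 13 parameters exactly from noise-free data", {
  recs <- simulate_mobilities(gt, design_grid(replicates = 1L), no_noise, seed = 3)
  sw <- fit_stepwise(recs)
  for (a in c("R", "C")) {
    g <- fit_global(recs[recs$analyte == a, ], stepwise_model(sw, a))
    truth <- analyte_params(gt[[a]])
    expect_true(g$converged)
    expect_equal(unname(g$estimate), unname(truth), tolerance = 1e-6)
    expect_identical(g$audit$n_fits, 1L)
    expect_identical(g$audit$n_parameters, 13L)
    expect_equal(length(g$residuals), nrow(recs) / 2)
    # covariance is symmetric positive semidefinite
    expect_equal(g$cov, t(g$cov), tolerance = 1e-8)
    expect_true(all(eigen(g$cov, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  }
})

test_that("the global objective is invariant to record ordering", {
  recs <- simulate_mobilities(gt["C"], design_grid(replicates = 2L),
                              noise_model(), seed = 4)
  sw <- fit_stepwise(recs)
  seedm <- stepwise_model(sw, "C")
  g1 <- fit_global(recs, seedm)
  set.seed(9)
  g2 <- fit_global(recs[sample(nrow(recs)), ], seedm)
  expect_equal(g1$objective, g2$objective, tolerance = 1e-9)
  expect_equal(g1$estimate, g2$estimate, tolerance = 1e-7)
})

test_that("structurally weak designs freeze the affected parameters", {
  recs <- simulate_mobilities(gt["C"], design_grid(replicates = 1L), no_noise, seed = 5)
  no_cd <- recs[recs$cCD == 0, ]
  expect_warning(g <- fit_global(no_cd, gt$C), "frozen")
  expect_true(all(c("pK_anion_CD", "eta_mu_CD") %in% g$frozen))
  expect_identical(unname(g$estimate["pK_anion_CD"]), -2.16)
  single_ph <- recs[recs$pH == 7, ]
  expect_warning(g2 <- fit_global(single_ph, gt$C), "frozen")
  expect_true(all(c("pKa0", "lam_a") %in% g2$frozen))
})
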