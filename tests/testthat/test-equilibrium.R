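test_that("water viscosity matches reference values and decreases with temperature", {
  expect_equal(water_viscosity(20), 1.002e-3, tolerance = 2e-3)
  th <- seq(-5, 85, by = 5)
  expect_true(all(diff(water_viscosity(th)) < 0))
  expect_true(all(water_viscosity(th) > 0))
  expect_identical(water_viscosity(26), water_viscosity(26))
  expect_error(water_viscosity(95), "range")
})

test_that("buffer viscosity applies the linear ligand correction", {
  v <- viscosity_model(epsilon = 8.2)
  expect_identical(buffer_viscosity(v, 0, 25), water_viscosity(25))
  expect_equal(buffer_viscosity(v, 0.015, 25) / water_viscosity(25), 1.123)
  expect_equal(buffer_viscosity(v, 0.100, 25) / water_viscosity(25), 1.82)
  expect_error(buffer_viscosity(v, -0.01, 25), "non-negative")
  expect_error(viscosity_model(epsilon = -1), "non-negative")
})

test_that("equilibrium constants follow the temperature linearization", {
  flat <- temp_linear_pk(-2.0, 0)
  expect_equal(k_at_temperature(flat, 15), k_at_temperature(flat, 37))
  p <- temp_linear_pk(-2.157, 0.0082)
  expect_equal(k_at_temperature(p, 26), 10^2.157, tolerance = 1e-12)
  expect_equal(k_at_temperature(p, 16) / k_at_temperature(p, 36),
               10^(0.0082 * 20), tolerance = 1e-12)
  expect_error(temp_linear_pk(0, 1.5), "range")
})

test_that("mobility product has the protonation and ligand limits", {
  m <- gt$C
  pKa <- m$pKa$pK0
  free <- mobility_product(m, conditions(26, pH = pKa + 5))
  expect_equal(free, m$eta_mu_free, tolerance = 1e-4)
  prot <- mobility_product(m, data.frame(theta = 26, pH = pKa - 5,
                                         cCD = 0, cmCD = 0))
  expect_lt(prot / m$eta_mu_free, 1e-4)
  # hand-computed value, caffeic acid with 15 mM CD at 26 C, pH 7
  expect_equal(mobility_product(m, conditions(26, 7, cCD = 0.015)),
               1.4118e-11, tolerance = 1e-4)
})

test_that("mobility product is monotone in pH and ligand concentration", {
  for (m in gt) {
    ph <- seq(2.5, 8, by = 0.25)
    vals <- mobility_product(m, data.frame(theta = 26, pH = ph, cCD = 0.01, cmCD = 0))
    expect_true(all(diff(vals) > 0))
    cc <- seq(0, 0.015, by = 0.001)
    vals <- mobility_product(m, data.frame(theta = 20, pH = 7, cCD = cc, cmCD = 0))
    expect_true(all(diff(vals) < 0))
    vals <- mobility_product(m, data.frame(theta = 31, pH = 5, cCD = 0, cmCD = cc))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("the half-mobility pH equals the apparent pKa", {
  m <- gt$R
  for (cc in c(0, 0.005, 0.015)) {
    K_an <- k_at_temperature(m$bind_anion_mCD, 20)
    K_ne <- k_at_temperature(m$bind_neutral_mCD, 20)
    pka <- pka_at_temperature(m$pKa, 20)
    pka_app <- apparent_pka(pka, K_ne, K_an, cc)
    plateau <- mobility_product(m, conditions(20, 13.9, cmCD = cc))
    half <- mobility_product(m, conditions(20, pka_app, cmCD = cc))
    expect_equal(half, plateau / 2, tolerance = 1e-9)
  }
})

test_that("mobility divides the product by the corrected viscosity", {
  m <- gt$C
  v <- viscosity_model()
  cond <- conditions(20, 7, cCD = 0.015)
  expect_equal(mobility(m, cond, v),
               mobility_product(m, cond) / buffer_viscosity(v, 0.015, 20))
  # raising temperature at fixed product increases mobility
  mu <- mobility(m, data.frame(theta = c(15, 37), pH = 7, cCD = 0, cmCD = 0), v)
  expect_gt(mu[2], mu[1] * water_viscosity(37) / water_viscosity(15) * 0.99)
})

test_that("apparent pKa shift reproduces the closed form", {
  expect_identical(apparent_pka(4.5, 100, 50, 0), 4.5)
  expect_equal(apparent_pka(4.5, 120, 120, 0.01), 4.5)
  expect_equal(apparent_pka(4.544, 10^3.097, 10^2.157, 0.015), 4.544 + 0.79692,
               tolerance = 1e-4)
  # shift is positive iff the neutral form binds more strongly
  expect_gt(apparent_pka(3, 200, 50, 0.01), 3)
  expect_lt(apparent_pka(3, 50, 200, 0.01), 3)
})

test_that("the thermodynamic cycle closes at every temperature", {
  set.seed(1)
  for (i in 1:25) {
    acid <- random_pk(); an <- random_pk(); ne <- random_pk()
    cx <- complex_acidity(acid, an, ne)
    for (th in c(15, 26, 37)) {
      lhs <- k_at_temperature(cx, th) * k_at_temperature(ne, th)
      rhs <- k_at_temperature(an, th) * k_at_temperature(acid, th)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("speciation closes mass balances and reproduces the constants", {
  set.seed(2)
  for (i in 1:20) {
    m <- gt[[sample(c("R", "C"), 1)]]
    cond <- conditions(runif(1, 15, 37), runif(1, 3, 7),
                       cCD = runif(1, 0, 0.015), cmCD = runif(1, 0, 0.1))
    x <- 10^runif(1, -5, -3.5)
    sp <- speciation(m, cond, x)
    x_sum <- sp$conc_XH + sp$conc_Xanion + sum(sp$conc_XHL) + sum(sp$conc_XanionL)
    expect_equal(x_sum, x, tolerance = 1e-11)
    for (lig in c("CD", "mCD")) {
      c_sum <- sp$conc_freeL[[lig]] + sp$conc_XHL[[lig]] + sp$conc_XanionL[[lig]]
      expect_equal(c_sum, sp$c_total[[lig]], tolerance = 1e-9)
      if (sp$c_total[[lig]] > 0) {
        K <- sp$conc_XanionL[[lig]] / (sp$conc_Xanion * sp$conc_freeL[[lig]])
        bk <- if (lig == "CD") m$bind_anion_CD else m$bind_anion_mCD
        expect_equal(K, k_at_temperature(bk, cond$theta), tolerance = 1e-9)
      }
    }
  }
})

test_that("speciation limits: vanishing analyte and zero binding", {
  m <- gt$C
  cond <- conditions(26, 5, cCD = 0.01)
  sp <- speciation(m, cond, 1e-12)
  expect_equal(sp$conc_freeL[["CD"]], 0.01, tolerance = 1e-9)
  # no binding: Henderson-Hasselbalch split of the free forms
  m0 <- analyte_model(
    eta_mu_free = m$eta_mu_free, pKa = m$pKa,
    bind_anion_CD = temp_linear_pk(12, 0), bind_anion_mCD = temp_linear_pk(12, 0),
    bind_neutral_CD = temp_linear_pk(12, 0), bind_neutral_mCD = temp_linear_pk(12, 0),
    eta_mu_complex_CD = m$eta_mu_free / 2, eta_mu_complex_mCD = m$eta_mu_free / 2)
  sp0 <- speciation(m0, conditions(26, 4.2, cCD = 0.01), 1e-4)
  r <- 10^(pka_at_temperature(m$pKa, 26) - 4.2)
  expect_equal(sp0$conc_XH / sp0$conc_Xanion, r, tolerance = 1e-6)
  expect_lt(sum(sp0$conc_XHL) + sum(sp0$conc_XanionL), 1e-12)
})

test_that("speciation converges to the ligand-excess closed form", {
  # depletion of free ligand is first-order in x/c: halving the ratio
  # halves the deviation, and at x/c = 1e-3 it is below 0.1%
  m <- gt$C
  cond <- conditions(20, 4.5, cmCD = 0.015)
  cf <- mobility_product(m, cond)
  err <- sapply(c(2e-3, 1e-3, 5e-4) * 0.015, function(x)
    abs(speciation(m, cond, x)$eta_mu_mix - cf) / cf)
  expect_lt(err[2], 1e-3)
  expect_equal(err[1] / err[2], 2, tolerance = 0.05)
  expect_equal(err[2] / err[3], 2, tolerance = 0.05)
})

test_that("condition validation rejects unphysical inputs", {
  expect_error(conditions(26, -1), "pH")
  expect_error(conditions(100, 7), "temperature")
  expect_error(conditions(26, 7, cCD = -1e-3), "non-negative")
  expect_error(analyte_model(1e-11, temp_linear_pk(4, 0),
                             temp_linear_pk(-2, 0), temp_linear_pk(-2, 0),
                             temp_linear_pk(-2, 0), temp_linear_pk(-2, 0),
                             2e-11, 0.5e-11), "below the free-anion")
})
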