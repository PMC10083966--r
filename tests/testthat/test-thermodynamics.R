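test_that("thermo_from_pk reproduces the closed-form decomposition", {
  # caffeic anion / CD binding
  t1 <- thermo_from_pk(temp_linear_pk(-2.16, 0.0060))
  expect_equal(t1$dH0 / 1000, -10.3, tolerance = 0.01)
  expect_equal(t1$dS0, 7, tolerance = 0.01)
  # neutral rosmarinic acid / mCD binding
  t2 <- thermo_from_pk(temp_linear_pk(-3.50, 0.017))
  expect_equal(t2$dH0 / 1000, -29, tolerance = 0.01)
  # athermal case
  t3 <- thermo_from_pk(temp_linear_pk(-2.5, 0))
  expect_identical(t3$dH0, 0)
  expect_equal(t3$dS0, log(10) * 8.314 * 2.5)
})

test_that("the Gibbs-Helmholtz closure holds for any parameter set", {
  set.seed(3)
  T0 <- ace_constants$T0
  for (i in 1:30) {
    tt <- thermo_from_pk(random_pk())
    expect_equal(tt$dG0_at_T0, tt$dH0 - T0 * tt$dS0, tolerance = 1e-9)
  }
})

test_that("pK(T) rebuilt from (dH, dS) re-linearizes to the same parameters", {
  R <- ace_constants$gas_constant
  T0 <- ace_constants$T0
  ln10 <- ace_constants$ln10
  set.seed(4)
  for (i in 1:10) {
    p <- random_pk()
    tt <- thermo_from_pk(p)
    TK <- seq(288, 310, length.out = 9)
    pk_exact <- tt$dH0 / (ln10 * R * TK) - tt$dS0 / (ln10 * R)
    fit <- lm(pk_exact ~ I(TK - T0))
    expect_lt(abs(unname(coef(fit)[1]) - p$pK0), 0.004)
    expect_lt(abs(unname(coef(fit)[2]) - p$lam), 2e-4)
    # curvature of the exact van't Hoff curve bounds the raw deviation:
    # |lam| * T0 * (dT/T0)^2 at the interval ends (plus ~4% of
    # higher-order terms)
    line <- p$pK0 + p$lam * (TK - T0)
    bound <- abs(p$lam) * T0 * max(abs(TK - T0) / T0)^2
    expect_lt(max(abs(pk_exact - line)), 1.1 * bound + 1e-9)
  }
})

test_that("standard errors propagate linearly (match finite differences)", {
  p <- temp_linear_pk(-2.157, 0.0082, se_pK0 = 0.008, se_lam = 0.0005,
                      cov_pK0_lam = -1e-6)
  tt <- thermo_from_pk(p)
  f <- function(pk0, lam) {
    x <- thermo_from_pk(temp_linear_pk(pk0, lam))
    c(x$dG0_at_T0, x$dH0, x$dS0)
  }
  h <- 1e-7
  J <- cbind((f(p$pK0 + h, p$lam) - f(p$pK0 - h, p$lam)) / (2 * h),
             (f(p$pK0, p$lam + h) - f(p$pK0, p$lam - h)) / (2 * h))
  V <- matrix(c(p$se_pK0^2, p$cov_pK0_lam, p$cov_pK0_lam, p$se_lam^2), 2)
  se_fd <- sqrt(diag(J %*% V %*% t(J)))
  expect_equal(tt$se_dG0, se_fd[1], tolerance = 1e-6)
  expect_equal(tt$se_dH0, se_fd[2], tolerance = 1e-6)
  expect_equal(tt$se_dS0, se_fd[3], tolerance = 1e-6)
})

test_that("contribution fractions decompose the Gibbs energy", {
  tt <- thermo_from_pk(temp_linear_pk(-2.16, 0.0060))
  fr <- contribution_fractions(tt)
  expect_equal(fr$xS + fr$xH, 1, tolerance = 1e-9)
  expect_equal(round(fr$xS, 2), 0.17)
  expect_equal(round(fr$xH, 2), 0.83)
  expect_equal(round(fr$rSH, 2), 0.20)
  # athermal: all free energy is enthalpic... entropic
  t0 <- thermo_from_pk(temp_linear_pk(-2.5, 0))
  fr0 <- suppressWarnings(contribution_fractions(t0))
  expect_equal(fr0$xH, 0)
  expect_equal(fr0$xS, 1)
  # zero-dH flags rSH undefined
  expect_warning(contribution_fractions(t0), "rSH")
})

test_that("complex acidity composes through the thermodynamic cycle", {
  # caffeic acid / mCD
  cx <- complex_acidity(temp_linear_pk(4.544, 0.0030),
                        temp_linear_pk(-2.157, 0.0082),
                        temp_linear_pk(-3.097, 0.0087))
  expect_equal(cx$pK0, 5.484, tolerance = 1e-9)
  expect_equal(cx$lam, 0.0030 + 0.0082 - 0.0087, tolerance = 1e-12)
  # rosmarinic acid / mCD
  cx2 <- complex_acidity(temp_linear_pk(2.997, 0.0114),
                         temp_linear_pk(-2.57, 0.008),
                         temp_linear_pk(-3.50, 0.017))
  expect_equal(cx2$pK0, 3.927, tolerance = 1e-9)
  # identical binding of both forms leaves the acidity unchanged
  b <- temp_linear_pk(-2.5, 0.01)
  same <- complex_acidity(temp_linear_pk(4.0, 0.002), b, b)
  expect_equal(same$pK0, 4.0)
  expect_equal(same$lam, 0.002)
})

test_that("Debye-Hueckel shift reproduces the printed corrections", {
  expect_identical(debye_huckel_shift(0), 0)
  expect_equal(debye_huckel_shift(0.010), 0.044, tolerance = 0.01)
  expect_equal(debye_huckel_shift(0.100), 0.11, tolerance = 0.01)
  I <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(debye_huckel_shift(I)) > 0))
  expect_error(debye_huckel_shift(-0.01), "non-negative")
})

test_that("Stokes radii follow from the mobility-viscosity product", {
  expect_equal(hydrodynamic_radius(2.056e-11, -1), 4.13e-10, tolerance = 1e-3)
  expect_equal(hydrodynamic_radius(1.486e-11, -1), 5.72e-10, tolerance = 1e-3)
  expect_lt(hydrodynamic_radius(1e-8, 1), 1e-12)
  expect_error(hydrodynamic_radius(2e-11, 0), "neutral")
})

test_that("thermo_table assembles the per-reaction report", {
  pk <- data.frame(reaction = c("C-.CD", "CH.mCD"),
                   pK0 = c(-2.16, -3.097), lam = c(0.0060, 0.0087),
                   se_pK0 = c(0.02, 0.008), se_lam = c(0.0006, 0.0008))
  tab <- thermo_table(pk)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dH0_kJ[1], -10.3, tolerance = 0.01)
  expect_equal(tab$dS0_J_K[2], 9, tolerance = 0.1)
  expect_equal(round(tab$rSH[2], 2), 0.19)
  expect_equal(tab$se_dH0_kJ[1], log(10) * 8.314 * 299^2 * 0.0006 / 1000)
})
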