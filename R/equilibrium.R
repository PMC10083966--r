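#' Physical constants and reference state
#'
#' Fixed constants used throughout the package.  The reference
#' temperature of the temperature linearization is `T0 = 299` K
#' (`theta0 = 26` degrees C), the median of the studied 15-37 degrees C
#' range.  Conversions between Celsius and Kelvin use 273.15; the 0.15 K
#' difference with the rounded reference convention is far below the
#' precision of any reported quantity.
#'
#' @format A list with elements `gas_constant` (J mol-1 K-1), `T0` (K),
#'   `theta0` (degrees C), `elementary_charge` (C), `ln10`.
#' @export
ace_constants <- list(
  gas_constant = 8.314,
  T0 = 299,
  theta0 = 26,
  elementary_charge = 1.602176634e-19,
  ln10 = log(10)
)

#' Experimental conditions of one electrophoretic run
#'
#' @param theta temperature in degrees C.
#' @param pH buffer pH at that temperature (activity scale).
#' @param cCD beta-cyclodextrin concentration, mol/L.
#' @param cmCD methyl-beta-cyclodextrin concentration, mol/L.
#' @param ionic_strength mol/L; the study design holds it at 10 mM.
#'
#' @return An object of class `ace_conditions`.
#' @export
conditions <- function(theta, pH, cCD = 0, cmCD = 0, ionic_strength = 0.010) {
  stopifnot(is.finite(theta), is.finite(pH), is.finite(cCD), is.finite(cmCD))
  if (theta < -10 || theta > 90) stop("temperature out of supported range [-10, 90] C")
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  if (cCD < 0 || cmCD < 0) stop("ligand concentrations must be non-negative")
  if (ionic_strength < 0) stop("ionic strength must be non-negative")
  structure(list(theta = theta, pH = pH, cCD = cCD, cmCD = cmCD,
                 ionic_strength = ionic_strength),
            class = "ace_conditions")
}

#' Temperature-linearized pK
#'
#' Local linearization `pK(theta) = pK0 + lam * (theta - theta0)` around
#' the reference temperature.  For binding equilibria the convention is
#' `K = 10^(-pK)`, so a positive slope `lam` means binding weakens on
#' heating (exothermic complexation).
#'
#' @param pK0 value at the reference temperature (dimensionless).
#' @param lam slope in K-1.
#' @param se_pK0,se_lam optional standard errors.
#' @param cov_pK0_lam optional covariance between the two estimates.
#'
#' @return An object of class `temp_linear_pk`.
#' @export
temp_linear_pk <- function(pK0, lam, se_pK0 = NA_real_, se_lam = NA_real_,
                           cov_pK0_lam = 0) {
  stopifnot(is.finite(pK0), is.finite(lam))
  if (abs(lam) >= 1) stop("|lam| >= 1 K-1 is outside any physically sensible range")
  structure(list(pK0 = pK0, lam = lam, se_pK0 = se_pK0, se_lam = se_lam,
                 cov_pK0_lam = cov_pK0_lam),
            class = "temp_linear_pk")
}

#' @export
print.temp_linear_pk <- function(x, ...) {
  cat(sprintf("pK(theta) = %.4f %+.5f * (theta - %g C)\n",
              x$pK0, x$lam, ace_constants$theta0))
  invisible(x)
}

#' Thirteen-parameter description of one analyte
#'
#' One analyte is characterized by its free-anion mobility-viscosity
#' product, an acid-dissociation pK pair, and, for each of the two
#' ligands (CD, mCD), a binding pK pair for the anionic form and one for
#' the neutral form plus the complex mobility-viscosity product: 13
#' scalars in total.
#'
#' @param eta_mu_free mobility-viscosity product of the free anion, N/V.
#' @param pKa acid [temp_linear_pk()] (pKa0, lambda_a).
#' @param bind_anion_CD,bind_anion_mCD [temp_linear_pk()] of the anion
#'   binding constants (pK0 convention `K = 10^-pK0`, so strong binding
#'   means a negative pK0).
#' @param bind_neutral_CD,bind_neutral_mCD same for the neutral form.
#' @param eta_mu_complex_CD,eta_mu_complex_mCD mobility-viscosity products
#'   of the anionic complexes, N/V; complexation increases the
#'   hydrodynamic radius, so these must be below `eta_mu_free`.
#'
#' @return An object of class `analyte_model`.
#' @export
analyte_model <- function(eta_mu_free, pKa,
                          bind_anion_CD, bind_anion_mCD,
                          bind_neutral_CD, bind_neutral_mCD,
                          eta_mu_complex_CD, eta_mu_complex_mCD) {
  stopifnot(inherits(pKa, "temp_linear_pk"),
            inherits(bind_anion_CD, "temp_linear_pk"),
            inherits(bind_anion_mCD, "temp_linear_pk"),
            inherits(bind_neutral_CD, "temp_linear_pk"),
            inherits(bind_neutral_mCD, "temp_linear_pk"))
  if (eta_mu_free <= 0 || eta_mu_complex_CD <= 0 || eta_mu_complex_mCD <= 0)
    stop("mobility-viscosity products must be positive")
  if (eta_mu_complex_CD >= eta_mu_free || eta_mu_complex_mCD >= eta_mu_free)
    stop("complex mobility-viscosity products must be below the free-anion product")
  structure(list(eta_mu_free = eta_mu_free, pKa = pKa,
                 bind_anion_CD = bind_anion_CD, bind_anion_mCD = bind_anion_mCD,
                 bind_neutral_CD = bind_neutral_CD, bind_neutral_mCD = bind_neutral_mCD,
                 eta_mu_complex_CD = eta_mu_complex_CD,
                 eta_mu_complex_mCD = eta_mu_complex_mCD),
            class = "analyte_model")
}

#' Viscosity model for cyclodextrin-containing buffers
#'
#' The buffer viscosity is modeled as `eta(c, theta) = (1 + epsilon * c)
#' * eta0(theta)` with `c` the total cyclodextrin concentration; no
#' distinction is made between CD and mCD, whose crowding effects were
#' found indistinguishable.  The default slope is `epsilon = 8.2` M-1.
#'
#' @param epsilon viscosity slope, M-1.
#' @param water_viscosity_correlation name of the pure-water correlation;
#'   only `"vogel"` is currently implemented.
#'
#' @return An object of class `viscosity_model`.
#' @export
viscosity_model <- function(epsilon = 8.2, water_viscosity_correlation = "vogel") {
  if (epsilon < 0) stop("epsilon must be non-negative")
  water_viscosity_correlation <- match.arg(water_viscosity_correlation, "vogel")
  structure(list(epsilon = epsilon,
                 water_viscosity_correlation = water_viscosity_correlation),
            class = "viscosity_model")
}

#' Pure-water viscosity
#'
#' Vogel-type correlation `eta0 = 2.414e-5 * 10^(247.8 / (T - 140))`
#' with T in kelvin, accurate to a few parts per thousand over 0-90
#' degrees C.  Absolute water viscosity only rescales mobilities into
#' mobility-viscosity products, so a small systematic offset of the
#' correlation cancels in every fitted parameter.
#'
#' @param theta temperature in degrees C (may be a vector).
#' @return viscosity in Pa s.
#' @export
#' @examples
#' water_viscosity(20)  # about 1.002e-3 Pa s
water_viscosity <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= -10) || any(theta >= 90))
    stop("temperature out of correlation range (-10, 90) C")
  TK <- theta + 273.15
  2.414e-5 * 10^(247.8 / (TK - 140))
}

#' Buffer viscosity with the ligand-concentration correction
#'
#' @param model a [viscosity_model()].
#' @param c_total total cyclodextrin concentration (CD + mCD), mol/L.
#' @param theta temperature in degrees C.
#' @return viscosity in Pa s.
#' @export
buffer_viscosity <- function(model, c_total, theta) {
  stopifnot(inherits(model, "viscosity_model"))
  if (any(c_total < 0)) stop("c_total must be non-negative")
  (1 + model$epsilon * c_total) * water_viscosity(theta)
}

#' Equilibrium constant at a given temperature
#'
#' For binding equilibria, `K(theta) = 10^(-pK0 - lam * (theta -
#' theta0))` in M-1.  For the acid the same linearization applies to the
#' pKa itself; use [pka_at_temperature()] when the pK value (not the
#' constant) is wanted.
#'
#' @param p a [temp_linear_pk()].
#' @param theta temperature in degrees C (vectorized).
#' @return equilibrium constant(s).
#' @export
k_at_temperature <- function(p, theta) {
  stopifnot(inherits(p, "temp_linear_pk"))
  10^(-pka_at_temperature(p, theta))
}

#' pK value at a given temperature
#'
#' @inheritParams k_at_temperature
#' @return pK value(s).
#' @export
pka_at_temperature <- function(p, theta) {
  stopifnot(inherits(p, "temp_linear_pk"))
  p$pK0 + p$lam * (theta - ace_constants$theta0)
}

#' Mobility-viscosity product of the analyte mixture
#'
#' Closed-form forward model under large ligand excess (free ligand
#' equal to total ligand): the population-averaged mobility-viscosity
#' product of the four-species system (neutral/anionic, free/bound per
#' ligand),
#' \deqn{\eta\mu = \frac{\eta\mu_{X^-} + \sum_L K_{X^-L} c_L \,
#'   \eta\mu_{X^-L}}{1 + 10^{pK_a - pH}(1 + \sum_L K_{XHL} c_L) +
#'   \sum_L K_{X^-L} c_L}}
#' Only the anionic species migrate, so the product falls towards zero
#' below the pKa and towards the complex value at high ligand excess.
#'
#' @param m an [analyte_model()].
#' @param cond an [ace_conditions][conditions()] object, or a data frame
#'   with columns `theta`, `pH`, `cCD`, `cmCD` (vectorized evaluation).
#' @return mobility-viscosity product(s), N/V.
#' @export
mobility_product <- function(m, cond) {
  stopifnot(inherits(m, "analyte_model"))
  if (inherits(cond, "ace_conditions")) cond <- as.data.frame(unclass(cond))
  th <- cond$theta
  r <- 10^(pka_at_temperature(m$pKa, th) - cond$pH)
  K_cd  <- k_at_temperature(m$bind_anion_CD, th)
  K_mcd <- k_at_temperature(m$bind_anion_mCD, th)
  Kh_cd  <- k_at_temperature(m$bind_neutral_CD, th)
  Kh_mcd <- k_at_temperature(m$bind_neutral_mCD, th)
  num <- m$eta_mu_free + K_cd * cond$cCD * m$eta_mu_complex_CD +
    K_mcd * cond$cmCD * m$eta_mu_complex_mCD
  den <- 1 + r + (Kh_cd * r + K_cd) * cond$cCD + (Kh_mcd * r + K_mcd) * cond$cmCD
  num / den
}

#' Observable electrophoretic mobility
#'
#' Mobility-viscosity product divided by the buffer viscosity.  Reported
#' as an absolute value: all analytes here are anions (negative signed
#' mobility) and the sign convention is dropped for readability.
#'
#' @inheritParams mobility_product
#' @param v a [viscosity_model()].
#' @return mobility magnitude(s), m2 V-1 s-1.
#' @export
mobility <- function(m, cond, v = viscosity_model()) {
  if (inherits(cond, "ace_conditions")) cond <- as.data.frame(unclass(cond))
  mobility_product(m, cond) /
    buffer_viscosity(v, cond$cCD + cond$cmCD, cond$theta)
}

#' Apparent pKa in the presence of a ligand
#'
#' Differential binding of the neutral and anionic forms shifts the pH
#' of half-mobility:
#' `pKa_app = pKa + log10((1 + K_neutral * c) / (1 + K_anion * c))`.
#'
#' @param pKa acid pKa without ligand.
#' @param K_neutral,K_anion 1:1 binding constants of the protonated and
#'   deprotonated forms, M-1.
#' @param c ligand concentration, mol/L.
#' @return apparent pKa.
#' @export
apparent_pka <- function(pKa, K_neutral, K_anion, c) {
  if (any(c < 0) || any(K_neutral < 0) || any(K_anion < 0))
    stop("concentrations and binding constants must be non-negative")
  pKa + log10((1 + K_neutral * c) / (1 + K_anion * c))
}

#' Exact speciation of the analyte/ligand system
#'
#' Solves the full mass-balance system (no ligand-excess approximation)
#' for one analyte distributed over neutral/anionic and free/bound forms
#' with up to two ligands.  Free-ligand concentrations are obtained by a
#' damped fixed-point iteration; the analyte balance is then closed in
#' closed form.  This solver is the internal oracle against which the
#' large-excess closed form [mobility_product()] is validated.
#'
#' @param m an [analyte_model()].
#' @param cond an [ace_conditions][conditions()]; `cCD`/`cmCD` are the
#'   total ligand concentrations.
#' @param x_total total analyte concentration, mol/L.
#' @param tol relative convergence tolerance on free-ligand
#'   concentrations.
#' @param max_iter iteration cap; exceeding it is an error.
#'
#' @return A list of class `speciation_state` with elements `conc_XH`,
#'   `conc_Xanion` (mol/L), `conc_XHL`, `conc_XanionL`, `conc_freeL`
#'   (named vectors over `c("CD", "mCD")`), the totals, and `eta_mu_mix`,
#'   the mixture mobility-viscosity product implied by the exact
#'   speciation.
#' @export
speciation <- function(m, cond, x_total, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(m, "analyte_model"), inherits(cond, "ace_conditions"))
  if (x_total <= 0) stop("x_total must be positive")
  th <- cond$theta
  r <- 10^(pka_at_temperature(m$pKa, th) - cond$pH)  # [XH]/[X-]
  Ka_L <- c(CD = k_at_temperature(m$bind_anion_CD, th),
            mCD = k_at_temperature(m$bind_anion_mCD, th))
  Kh_L <- c(CD = k_at_temperature(m$bind_neutral_CD, th),
            mCD = k_at_temperature(m$bind_neutral_mCD, th))
  c_tot <- c(CD = cond$cCD, mCD = cond$cmCD)
  eff <- Ka_L + r * Kh_L  # per-ligand effective affinity of the X- pool
  L <- c_tot
  damp <- 0.5
  for (it in seq_len(max_iter)) {
    D <- 1 + r + sum(eff * L)
    Xa <- x_total / D
    Lnew <- c_tot / (1 + Xa * eff)
    delta <- max(abs(Lnew - L) / pmax(L, .Machine$double.xmin))
    L <- damp * Lnew + (1 - damp) * L
    if (delta < tol || all(c_tot == 0)) {
      L <- Lnew
      break
    }
    if (it == max_iter)
      stop(sprintf("speciation did not converge in %d iterations (last delta %.3e)",
                   max_iter, delta))
  }
  D <- 1 + r + sum(eff * L)
  Xa <- x_total / D
  XH <- r * Xa
  XaL <- Xa * Ka_L * L
  XHL <- XH * Kh_L * L
  eta_mu_mix <- (Xa * m$eta_mu_free +
                   XaL[["CD"]] * m$eta_mu_complex_CD +
                   XaL[["mCD"]] * m$eta_mu_complex_mCD) / x_total
  structure(list(conc_XH = XH, conc_Xanion = Xa, conc_XHL = XHL,
                 conc_XanionL = XaL, conc_freeL = L,
                 x_total = x_total, c_total = c_tot,
                 eta_mu_mix = eta_mu_mix),
            class = "speciation_state")
}
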