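#' Reaction thermodynamics from a temperature-linearized pK
#'
#' The linearization `pK(T) = pK0 + lam * (T - T0)` of `-log10 K` around
#' the reference temperature determines the standard reaction enthalpy
#' and entropy in closed form (van't Hoff relation, assuming both are
#' temperature-independent over the narrow studied range):
#' \deqn{\Delta_r H^0 = -\ln 10 \cdot \lambda R T_0^2, \qquad
#'   \Delta_r S^0 = -\ln 10 \cdot R (pK_0 + \lambda T_0), \qquad
#'   \Delta_r G^0(T_0) = \ln 10 \cdot R T_0\, pK_0.}
#' Standard errors, when present on the input, are propagated by
#' first-order linearization; the covariance between `pK0` and `lam` is
#' used when supplied.
#'
#' @param p a [temp_linear_pk()].
#' @return A list of class `thermo_triple` with `dG0_at_T0`, `dH0`
#'   (J/mol), `dS0` (J K-1 mol-1) and their standard errors.
#' @export
#' @examples
#' thermo_from_pk(temp_linear_pk(-2.16, 0.0060))  # anion binding, exothermic
thermo_from_pk <- function(p) {
  stopifnot(inherits(p, "temp_linear_pk"))
  R <- ace_constants$gas_constant
  T0 <- ace_constants$T0
  ln10 <- ace_constants$ln10
  dH <- -ln10 * p$lam * R * T0^2
  dS <- -ln10 * R * (p$pK0 + p$lam * T0)
  dG <- ln10 * R * T0 * p$pK0
  cov <- if (is.finite(p$cov_pK0_lam)) p$cov_pK0_lam else 0
  se_dH <- ln10 * R * T0^2 * p$se_lam
  se_dS <- ln10 * R * sqrt(p$se_pK0^2 + (T0 * p$se_lam)^2 + 2 * T0 * cov)
  se_dG <- ln10 * R * T0 * p$se_pK0
  structure(list(dG0_at_T0 = dG, dH0 = dH, dS0 = dS,
                 se_dG0 = se_dG, se_dH0 = se_dH, se_dS0 = se_dS),
            class = "thermo_triple")
}

#' @export
print.thermo_triple <- function(x, ...) {
  cat(sprintf("dG0(T0) = %8.2f kJ/mol   dH0 = %8.2f kJ/mol   dS0 = %8.2f J/K/mol\n",
              x$dG0_at_T0 / 1000, x$dH0 / 1000, x$dS0))
  invisible(x)
}

#' Entropic and enthalpic contribution fractions
#'
#' Decomposition of the standard Gibbs energy at the reference
#' temperature: `xS = -T0 dS0 / dG0` (entropic fraction), `xH = dH0 /
#' dG0` (enthalpic fraction, `xS + xH = 1` by construction) and `rSH =
#' -T0 dS0 / dH0`, the entropy-to-enthalpy ratio.
#'
#' @param t a [thermo_from_pk()] result.
#' @return A list of class `contribution_fractions` with `xS`, `xH`,
#'   `rSH`; a zero denominator yields `NaN` with an `undefined`
#'   attribute naming the affected ratio(s).
#' @export
contribution_fractions <- function(t) {
  stopifnot(inherits(t, "thermo_triple"))
  T0 <- ace_constants$T0
  undefined <- character(0)
  if (t$dG0_at_T0 == 0) undefined <- c(undefined, "xS", "xH")
  if (t$dH0 == 0) undefined <- c(undefined, "rSH")
  out <- list(xS = -T0 * t$dS0 / t$dG0_at_T0,
              xH = t$dH0 / t$dG0_at_T0,
              rSH = -T0 * t$dS0 / t$dH0)
  if (length(undefined)) {
    out[undefined] <- NaN
    warning("undefined contribution ratio(s): ", paste(undefined, collapse = ", "))
  }
  structure(c(out, list(undefined = undefined)), class = "contribution_fractions")
}

#' Acidity of the host-guest complex from the thermodynamic cycle
#'
#' The four equilibria (acid dissociation of free and bound analyte,
#' binding of the anionic and neutral forms) form a closed cycle, so the
#' complex acidity follows from the other three:
#' `Ka_complex = Ka * K_anion / K_neutral`, i.e. on the pK scale
#' `pK0_out = pKa0 + pK0_anion - pK0_neutral` (and likewise for the
#' slopes).  Standard errors combine in quadrature (fit covariances
#' between distinct equilibria are not tracked).
#'
#' @param acid acid [temp_linear_pk()].
#' @param bind_anion,bind_neutral binding [temp_linear_pk()] of the
#'   anionic and neutral forms.
#' @return A [temp_linear_pk()] for the complexed acid.
#' @export
complex_acidity <- function(acid, bind_anion, bind_neutral) {
  stopifnot(inherits(acid, "temp_linear_pk"),
            inherits(bind_anion, "temp_linear_pk"),
            inherits(bind_neutral, "temp_linear_pk"))
  temp_linear_pk(
    pK0 = acid$pK0 + bind_anion$pK0 - bind_neutral$pK0,
    lam = acid$lam + bind_anion$lam - bind_neutral$lam,
    se_pK0 = sqrt(acid$se_pK0^2 + bind_anion$se_pK0^2 + bind_neutral$se_pK0^2),
    se_lam = sqrt(acid$se_lam^2 + bind_anion$se_lam^2 + bind_neutral$se_lam^2)
  )
}

#' Debye-Hueckel pKa correction to zero ionic strength
#'
#' Additive correction for extrapolating the pKa of a monoprotic acid
#' (singly charged anion) from ionic strength `I` to infinite dilution,
#' using the extended Debye-Hueckel form `A sqrt(I) / (1 + 1.5 sqrt(I))`
#' with `A = 0.509` (25 degrees C value; the temperature dependence of A
#' is negligible against the reported errors).
#'
#' @param I ionic strength, mol/L.
#' @param theta temperature in degrees C (accepted for interface
#'   symmetry; A is held at its 25 C value).
#' @return additive pKa shift (apply as `pKa(I=0) = pKa(I) + shift`).
#' @export
#' @examples
#' debye_huckel_shift(0.010)  # about +0.044
#' debye_huckel_shift(0.100)  # about +0.11
debye_huckel_shift <- function(I, theta = 25) {
  if (any(I < 0)) stop("ionic strength must be non-negative")
  A <- 0.509
  A * sqrt(I) / (1 + 1.5 * sqrt(I))
}

#' Equivalent hydrodynamic (Stokes) radius from a mobility product
#'
#' In the low-ionic-strength limit `mu = q / (6 pi eta Re)`, so the
#' temperature-invariant mobility-viscosity product gives `Re = |z| e /
#' (6 pi eta_mu)`.  No ionic-strength correction is applied: at finite
#' ionic strength the plain Stokes formula systematically overestimates
#' the radius by a few tenths of an angstrom.
#'
#' @param eta_mu mobility-viscosity product, N/V.
#' @param charge_number signed integer charge; must be non-zero.
#' @return radius in m.
#' @export
hydrodynamic_radius <- function(eta_mu, charge_number) {
  if (any(eta_mu <= 0)) stop("eta_mu must be positive")
  if (any(charge_number == 0)) stop("neutral species have no electrophoretic radius")
  abs(charge_number) * ace_constants$elementary_charge / (6 * pi * eta_mu)
}

#' Thermodynamic table for a set of equilibria
#'
#' Applies [thermo_from_pk()] and [contribution_fractions()] to each row
#' of a pK parameter table, producing the standard report layout:
#' pK(T0), dG0(T0), dH0, dS0 (with standard errors) and the contribution
#' fractions.
#'
#' @param pk_table data frame with columns `reaction`, `pK0`, `lam` and
#'   optionally `se_pK0`, `se_lam`, `cov_pK0_lam`.
#' @return data frame with one row per reaction; energies in kJ/mol,
#'   entropies in J K-1 mol-1.
#' @export
thermo_table <- function(pk_table) {
  stopifnot(is.data.frame(pk_table),
            all(c("reaction", "pK0", "lam") %in% names(pk_table)))
  n <- nrow(pk_table)
  get0 <- function(col, default) {
    if (col %in% names(pk_table)) pk_table[[col]] else rep(default, n)
  }
  se_pk0 <- get0("se_pK0", NA_real_)
  se_lam <- get0("se_lam", NA_real_)
  covpl <- get0("cov_pK0_lam", 0)
  rows <- lapply(seq_len(n), function(i) {
    p <- temp_linear_pk(pk_table$pK0[i], pk_table$lam[i],
                        se_pk0[i], se_lam[i], covpl[i])
    tt <- thermo_from_pk(p)
    fr <- contribution_fractions(tt)
    data.frame(reaction = pk_table$reaction[i],
               pK_T0 = p$pK0, se_pK_T0 = p$se_pK0,
               dG0_kJ = tt$dG0_at_T0 / 1000, se_dG0_kJ = tt$se_dG0 / 1000,
               dH0_kJ = tt$dH0 / 1000, se_dH0_kJ = tt$se_dH0 / 1000,
               dS0_J_K = tt$dS0, se_dS0_J_K = tt$se_dS0,
               xS = fr$xS, xH = fr$xH, rSH = fr$rSH)
  })
  do.call(rbind, rows)
}
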