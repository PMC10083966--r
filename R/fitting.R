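## Estimation procedures: the stepwise sequence of small fits and the
## per-analyte 13-parameter global fit.  All fits act on the
## mobility-viscosity product (units of 1e-11 N/V internally, so every
## parameter is O(1) for the optimizer) with unweighted least squares;
## binding and acidity constants are parameterized on the pK (log10)
## scale, which also enforces positivity of the constants.

# observed mobility-viscosity products on the 1e-11 N/V scale
.obs_eta_mu <- function(records, v = viscosity_model()) {
  records$mobility *
    buffer_viscosity(v, records$cCD + records$cmCD, records$theta) * 1e11
}

# forward model of Eq.-19 type on the 13-parameter vector (1e-11 scale)
.predict_eta_mu <- function(p, data) {
  dth <- data$theta - ace_constants$theta0
  r <- 10^(p[["pKa0"]] + p[["lam_a"]] * dth - data$pH)
  K_cd <- 10^(-p[["pK_anion_CD"]] - p[["lam_anion_CD"]] * dth)
  K_mcd <- 10^(-p[["pK_anion_mCD"]] - p[["lam_anion_mCD"]] * dth)
  Kh_cd <- 10^(-p[["pK_neutral_CD"]] - p[["lam_neutral_CD"]] * dth)
  Kh_mcd <- 10^(-p[["pK_neutral_mCD"]] - p[["lam_neutral_mCD"]] * dth)
  num <- p[["eta_mu_free"]] + K_cd * data$cCD * p[["eta_mu_CD"]] +
    K_mcd * data$cmCD * p[["eta_mu_mCD"]]
  den <- 1 + r * (1 + Kh_cd * data$cCD + Kh_mcd * data$cmCD) +
    K_cd * data$cCD + K_mcd * data$cmCD
  num / den
}

# numeric Jacobian of a residual function (central differences)
.num_jacobian <- function(fn, par, rel_step = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- rel_step * max(abs(par[j]), 1e-3)
    pp <- pm <- par
    pp[j] <- par[j] + h
    pm[j] <- par[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  colnames(J) <- names(par)
  J
}

# solve(JtJ) with an SVD pseudo-inverse fallback for near-singular fits
.safe_inverse <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(A)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Levenberg-Marquardt least squares with covariance = (JtJ)^-1 * s^2
.lm_least_squares <- function(start, resid_fn,
                              lower = rep(-Inf, length(start)),
                              upper = rep(Inf, length(start))) {
  out <- minpack.lm::nls.lm(
    par = start, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, maxfev = 5000, ftol = 1e-12, ptol = 1e-12, gtol = 0))
  par <- out$par
  res <- out$fvec
  n <- length(res)
  k <- length(par)
  rss <- sum(res^2)
  s2 <- if (n > k) rss / (n - k) else 0
  J <- .num_jacobian(resid_fn, par)
  cov <- s2 * .safe_inverse(crossprod(J))
  dimnames(cov) <- list(names(par), names(par))
  se <- sqrt(pmax(diag(as.matrix(cov)), 0))
  names(se) <- names(par)
  list(par = par, se = se, cov = cov, residuals = -res, rss = rss,
       n = n, converged = out$info %in% 1:4, info = out$info,
       niter = out$niter, message = out$message)
}

#' Step 1: free-anion mobility-viscosity product
#'
#' Averages the viscosity-corrected mobility over all records at pH 7
#' without ligand, where the analytes are fully deprotonated and
#' unbound.  The product is expected to be temperature-independent, so
#' records from all temperatures are pooled; the spread across
#' temperatures relative to the within-temperature spread is the check
#' of that hypothesis.
#'
#' @param records measurement data frame (internal units); rows at pH 7
#'   with `cCD = cmCD = 0` are selected automatically.
#' @param v a [viscosity_model()].
#' @return data frame with one row per analyte: `eta_mu` (1e-11 N/V),
#'   `sd` (between-record spread), `se` (standard error of the mean),
#'   `n`, `n_temperatures`.
#' @export
fit_step1 <- function(records, v = viscosity_model()) {
  sel <- records[records$pH == 7 & records$cCD == 0 & records$cmCD == 0, ]
  if (nrow(sel) == 0) stop("no pH-7 ligand-free records for step 1")
  out <- do.call(rbind, lapply(split(sel, sel$analyte), function(d) {
    if (length(unique(d$theta)) < 2)
      stop("step 1 needs records at >= 2 temperatures")
    y <- .obs_eta_mu(d, v)
    data.frame(analyte = d$analyte[1], eta_mu = mean(y), sd = sd(y),
               se = sd(y) / sqrt(length(y)), n = length(y),
               n_temperatures = length(unique(d$theta)))
  }))
  rownames(out) <- NULL
  out
}

#' Step 2: binding isotherm of the anionic form at pH 7
#'
#' Fits the 1:1 isotherm `eta_mu(c) = (eta_mu_X + K c eta_mu_XL) / (1 +
#' K c)` over ligand concentration at one temperature, with the
#' free-anion product held at its step-1 value.  The binding constant is
#' fitted as `pK = -log10 K`.
#'
#' @param records rows for one analyte, one ligand, one temperature, at
#'   pH 7 (any zero-ligand rows are used as-is; at least two distinct
#'   positive concentrations are required since the free-anion product
#'   is fixed).
#' @param eta_mu_free step-1 estimate, 1e-11 N/V.
#' @param ligand `"CD"` or `"mCD"` — selects which concentration column
#'   drives the isotherm.
#' @param v a [viscosity_model()].
#' @return list with `pK_anion`, `se_pK_anion`, `K_anion`,
#'   `eta_mu_complex`, `se_eta_mu_complex` (1e-11 N/V), `cov`,
#'   `converged`, `residuals`, `n`.
#' @export
fit_step2 <- function(records, eta_mu_free, ligand = c("CD", "mCD"),
                      v = viscosity_model()) {
  ligand <- match.arg(ligand)
  cc <- if (ligand == "CD") records$cCD else records$cmCD
  if (length(unique(cc[cc > 0])) < 2)
    stop("step 2 needs >= 2 distinct positive ligand concentrations")
  y <- .obs_eta_mu(records, v)
  resid_fn <- function(p) {
    K <- 10^(-p[["pK"]])
    (eta_mu_free + K * cc * p[["emc"]]) / (1 + K * cc) - y
  }
  start <- c(pK = -2, emc = max(min(y), 0.1 * eta_mu_free))
  fit <- .lm_least_squares(start, resid_fn,
                           lower = c(-8, 1e-6), upper = c(4, eta_mu_free * 2))
  if (!fit$converged)
    warning("step-2 fit did not converge (info ", fit$info, ")")
  list(pK_anion = unname(fit$par["pK"]), se_pK_anion = unname(fit$se["pK"]),
       K_anion = 10^(-unname(fit$par["pK"])),
       eta_mu_complex = unname(fit$par["emc"]),
       se_eta_mu_complex = unname(fit$se["emc"]),
       cov = fit$cov, converged = fit$converged,
       residuals = fit$residuals, n = fit$n)
}

#' Step 3: apparent pKa from the pH dependence
#'
#' One-parameter logistic fit of `eta_mu(pH) = eta_mu_X7 / (1 +
#' 10^(pKa_app - pH))` at fixed ligand concentration, with the pH-7
#' plateau held fixed.  With no ligand the apparent pKa is the acid pKa;
#' with ligand the shift gives the neutral-form binding constant via
#' [apparent_pka()] inversion (see [fit_stepwise()]).
#'
#' @param records rows for one analyte and ligand state across pH, one
#'   temperature; needs >= 4 distinct pH values.
#' @param eta_mu_x7 plateau mobility-viscosity product at pH 7 for this
#'   ligand state, 1e-11 N/V.
#' @param v a [viscosity_model()].
#' @return list with `pKa_app`, `se_pKa_app`, `converged`, `residuals`,
#'   `n`.
#' @export
fit_step3 <- function(records, eta_mu_x7, v = viscosity_model()) {
  if (length(unique(records$pH)) < 4)
    stop("step 3 needs >= 4 distinct pH values spanning the transition")
  y <- .obs_eta_mu(records, v)
  resid_fn <- function(p) eta_mu_x7 / (1 + 10^(p[["pKa_app"]] - records$pH)) - y
  # start near the pH of half-plateau
  half <- abs(y - eta_mu_x7 / 2)
  start <- c(pKa_app = records$pH[which.min(half)])
  fit <- .lm_least_squares(start, resid_fn, lower = 0.5, upper = 13.5)
  if (!fit$converged)
    warning("step-3 fit did not converge (info ", fit$info, ")")
  list(pKa_app = unname(fit$par["pKa_app"]),
       se_pKa_app = unname(fit$se["pKa_app"]),
       converged = fit$converged, residuals = fit$residuals, n = fit$n)
}

#' Linearize pK estimates against temperature
#'
#' Weighted linear regression of pK values on `theta - theta0`
#' (inverse-variance weights when standard errors are supplied and all
#' positive, unweighted otherwise), returning a [temp_linear_pk()] with
#' standard errors and the estimate covariance.
#'
#' @param pk pK values.
#' @param theta temperatures, degrees C.
#' @param se optional standard errors of `pk`.
#' @return a [temp_linear_pk()].
#' @export
linearize_pk <- function(pk, theta, se = NULL) {
  if (length(pk) < 3) stop("need >= 3 temperatures to linearize pK(T)")
  dth <- theta - ace_constants$theta0
  w <- if (!is.null(se) && all(is.finite(se)) && all(se > 0)) 1 / se^2 else NULL
  fit <- if (is.null(w)) lm(pk ~ dth) else lm(pk ~ dth, weights = w)
  cf <- coef(fit)
  # exact-line inputs give a zero-residual fit; the summary warning for
  # that case is expected, and the (zero) errors are correct
  V <- suppressWarnings(vcov(fit))
  temp_linear_pk(pK0 = unname(cf[1]), lam = unname(cf[2]),
                 se_pK0 = sqrt(V[1, 1]), se_lam = sqrt(V[2, 2]),
                 cov_pK0_lam = V[1, 2])
}

#' Stepwise estimation pipeline
#'
#' Runs the full three-step procedure over a measurement table: (1) the
#' free-anion mobility-viscosity product per analyte; (2) per (analyte,
#' ligand, temperature) binding isotherms at pH 7; (3) per (analyte,
#' ligand state, temperature) apparent-pKa fits over pH, from which the
#' acid pKa (no ligand) and the neutral-form binding constants (via the
#' apparent-pKa shift) follow.  Each pK family is then linearized
#' against temperature, and complex mobility products are combined
#' across temperatures by inverse-variance averaging.  An audit of the
#' number of independent fits and fitted parameters is attached.
#'
#' @param records measurement data frame (internal units, both
#'   analytes).
#' @param v a [viscosity_model()].
#' @return An object of class `stepwise_results` with data-frame
#'   elements `step1`, `step2`, `step3`, `linear`, `eta_mu` and a list
#'   `audit` (`n_fits`, `n_parameters`).
#' @export
fit_stepwise <- function(records, v = viscosity_model()) {
  s1 <- fit_step1(records, v)
  analytes <- s1$analyte
  ph7 <- records[records$pH == 7, ]

  ## step 2: binding isotherms at pH 7
  s2 <- list()
  for (a in analytes) {
    emf <- s1$eta_mu[s1$analyte == a]
    for (lig in c("CD", "mCD")) {
      other <- if (lig == "CD") ph7$cmCD else ph7$cCD
      cc <- if (lig == "CD") ph7$cCD else ph7$cmCD
      sub <- ph7[ph7$analyte == a & other == 0, ]
      for (th in sort(unique(sub$theta))) {
        d <- sub[sub$theta == th, ]
        f <- fit_step2(d, emf, lig, v)
        s2[[length(s2) + 1L]] <- data.frame(
          analyte = a, ligand = lig, theta = th,
          pK_anion = f$pK_anion, se_pK_anion = f$se_pK_anion,
          eta_mu_complex = f$eta_mu_complex,
          se_eta_mu_complex = f$se_eta_mu_complex,
          converged = f$converged)
      }
    }
  }
  s2 <- do.call(rbind, s2)

  ## step 3: apparent pKa over pH at the scan ligand states
  states <- unique(records[records$pH < 7,
                           c("analyte", "cCD", "cmCD")])
  s3 <- list()
  for (i in seq_len(nrow(states))) {
    a <- states$analyte[i]
    ccd <- states$cCD[i]
    cmcd <- states$cmCD[i]
    state <- if (ccd > 0) "CD" else if (cmcd > 0) "mCD" else "none"
    c_lig <- max(ccd, cmcd)
    sub <- records[records$analyte == a & records$cCD == ccd &
                     records$cmCD == cmcd, ]
    emf <- s1$eta_mu[s1$analyte == a]
    for (th in sort(unique(sub$theta))) {
      d <- sub[sub$theta == th, ]
      em_x7 <- if (state == "none") emf else {
        p2 <- s2[s2$analyte == a & s2$ligand == state & s2$theta == th, ]
        K <- 10^(-p2$pK_anion)
        (emf + K * c_lig * p2$eta_mu_complex) / (1 + K * c_lig)
      }
      f <- fit_step3(d, em_x7, v)
      s3[[length(s3) + 1L]] <- data.frame(
        analyte = a, state = state, c_ligand = c_lig, theta = th,
        pKa_app = f$pKa_app, se_pKa_app = f$se_pKa_app,
        converged = f$converged)
    }
  }
  s3 <- do.call(rbind, s3)

  ## derive neutral-form binding constants from the apparent-pKa shifts
  s3$pK_neutral <- NA_real_
  s3$se_pK_neutral <- NA_real_
  ln10 <- ace_constants$ln10
  for (i in which(s3$state != "none")) {
    a <- s3$analyte[i]; th <- s3$theta[i]; lig <- s3$state[i]
    cc <- s3$c_ligand[i]
    base <- s3[s3$analyte == a & s3$state == "none" & s3$theta == th, ]
    p2 <- s2[s2$analyte == a & s2$ligand == lig & s2$theta == th, ]
    dpk <- s3$pKa_app[i] - base$pKa_app
    Ka <- 10^(-p2$pK_anion)
    Kh <- (10^dpk * (1 + Ka * cc) - 1) / cc
    if (Kh <= 0) {
      warning(sprintf("non-physical neutral binding constant (%s, %s, %g C); floored at 0",
                      a, lig, th))
      Kh <- 0
      s3$pK_neutral[i] <- Inf
      next
    }
    var_dpk <- s3$se_pKa_app[i]^2 + base$se_pKa_app^2
    se_Ka <- ln10 * Ka * p2$se_pK_anion
    dKh_ddpk <- ln10 * 10^dpk * (1 + Ka * cc) / cc
    dKh_dKa <- 10^dpk
    se_Kh <- sqrt(dKh_ddpk^2 * var_dpk + dKh_dKa^2 * se_Ka^2)
    s3$pK_neutral[i] <- -log10(Kh)
    s3$se_pK_neutral[i] <- se_Kh / (ln10 * Kh)
  }

  ## temperature linearization per equilibrium
  lin <- list()
  for (a in analytes) {
    base <- s3[s3$analyte == a & s3$state == "none", ]
    lin[[length(lin) + 1L]] <- data.frame(analyte = a, equilibrium = "acid",
                                          .pk_row(linearize_pk(base$pKa_app, base$theta, base$se_pKa_app)))
    for (lig in c("CD", "mCD")) {
      p2 <- s2[s2$analyte == a & s2$ligand == lig, ]
      lin[[length(lin) + 1L]] <- data.frame(
        analyte = a, equilibrium = paste0("anion_", lig),
        .pk_row(linearize_pk(p2$pK_anion, p2$theta, p2$se_pK_anion)))
      p3 <- s3[s3$analyte == a & s3$state == lig & is.finite(s3$pK_neutral), ]
      lin[[length(lin) + 1L]] <- data.frame(
        analyte = a, equilibrium = paste0("neutral_", lig),
        .pk_row(linearize_pk(p3$pK_neutral, p3$theta, p3$se_pK_neutral)))
    }
  }
  lin <- do.call(rbind, lin)

  ## mobility products: step-1 free anion; inverse-variance averaged complexes
  emu <- list()
  for (a in analytes) {
    emu[[length(emu) + 1L]] <- data.frame(
      analyte = a, species = "free",
      eta_mu = s1$eta_mu[s1$analyte == a], se = s1$se[s1$analyte == a])
    for (lig in c("CD", "mCD")) {
      p2 <- s2[s2$analyte == a & s2$ligand == lig, ]
      w <- 1 / pmax(p2$se_eta_mu_complex, 1e-12)^2
      emu[[length(emu) + 1L]] <- data.frame(
        analyte = a, species = lig,
        eta_mu = sum(w * p2$eta_mu_complex) / sum(w),
        se = sqrt(1 / sum(w)))
    }
  }
  emu <- do.call(rbind, emu)

  audit <- list(n_fits = nrow(s1) + nrow(s2) + nrow(s3),
                n_parameters = nrow(s1) + 2L * nrow(s2) + nrow(s3))
  structure(list(step1 = s1, step2 = s2, step3 = s3, linear = lin,
                 eta_mu = emu, audit = audit),
            class = "stepwise_results")
}

.pk_row <- function(p) {
  data.frame(pK0 = p$pK0, se_pK0 = p$se_pK0, lam = p$lam, se_lam = p$se_lam,
             cov_pK0_lam = p$cov_pK0_lam)
}

#' @export
print.stepwise_results <- function(x, ...) {
  cat(sprintf("Stepwise fit: %d independent fits, %d fitted parameters\n",
              x$audit$n_fits, x$audit$n_parameters))
  print(x$linear, digits = 4)
  invisible(x)
}

#' Analyte model from stepwise results
#'
#' Assembles the 13-parameter [analyte_model()] for one analyte from a
#' [fit_stepwise()] result, e.g. for seeding [fit_global()].
#'
#' @param sw a `stepwise_results` object.
#' @param analyte analyte id.
#' @return an [analyte_model()].
#' @export
stepwise_model <- function(sw, analyte) {
  stopifnot(inherits(sw, "stepwise_results"))
  lin <- sw$linear[sw$linear$analyte == analyte, ]
  emu <- sw$eta_mu[sw$eta_mu$analyte == analyte, ]
  getpk <- function(eq) {
    r <- lin[lin$equilibrium == eq, ]
    temp_linear_pk(r$pK0, r$lam, r$se_pK0, r$se_lam, r$cov_pK0_lam)
  }
  getem <- function(sp) emu$eta_mu[emu$species == sp] * 1e-11
  analyte_model(eta_mu_free = getem("free"), pKa = getpk("acid"),
                bind_anion_CD = getpk("anion_CD"),
                bind_anion_mCD = getpk("anion_mCD"),
                bind_neutral_CD = getpk("neutral_CD"),
                bind_neutral_mCD = getpk("neutral_mCD"),
                eta_mu_complex_CD = getem("CD"),
                eta_mu_complex_mCD = getem("mCD"))
}

#' Stepwise estimates and standard errors as a 13-parameter vector
#'
#' Returns the stepwise results for one analyte in the layout of
#' [analyte_params()], with matching standard errors — convenient for
#' head-to-head precision comparisons with the global fit.
#'
#' @inheritParams stepwise_model
#' @return list with named vectors `estimate` and `se`.
#' @export
stepwise_params <- function(sw, analyte) {
  m <- stepwise_model(sw, analyte)
  est <- analyte_params(m)
  lin <- sw$linear[sw$linear$analyte == analyte, ]
  emu <- sw$eta_mu[sw$eta_mu$analyte == analyte, ]
  pick <- function(eq, col) lin[lin$equilibrium == eq, col]
  se <- c(eta_mu_free = emu$se[emu$species == "free"],
          pKa0 = pick("acid", "se_pK0"), lam_a = pick("acid", "se_lam"),
          pK_anion_CD = pick("anion_CD", "se_pK0"),
          lam_anion_CD = pick("anion_CD", "se_lam"),
          eta_mu_CD = emu$se[emu$species == "CD"],
          pK_anion_mCD = pick("anion_mCD", "se_pK0"),
          lam_anion_mCD = pick("anion_mCD", "se_lam"),
          eta_mu_mCD = emu$se[emu$species == "mCD"],
          pK_neutral_CD = pick("neutral_CD", "se_pK0"),
          lam_neutral_CD = pick("neutral_CD", "se_lam"),
          pK_neutral_mCD = pick("neutral_mCD", "se_pK0"),
          lam_neutral_mCD = pick("neutral_mCD", "se_lam"))
  list(estimate = est, se = se[names(est)])
}

#' Global 13-parameter fit for one analyte
#'
#' Single Levenberg-Marquardt least-squares fit of all records of one
#' analyte over pH, temperature and both ligand concentrations,
#' minimizing unweighted squared residuals of the mobility-viscosity
#' product.  Each record enters the objective exactly once.  Standard
#' errors come from the covariance `(J'J)^-1 s2` at the optimum, with
#' `s2` the residual variance.
#'
#' Identifiability pre-flight: a ligand's four parameters require at
#' least two distinct positive concentration levels of that ligand, and
#' the acid pair requires at least three distinct pH values; parameters
#' failing the check are frozen at their seed values with a warning.
#'
#' Weighting: the default (`"none"`) minimizes plain squared residuals,
#' the convention of the reference protocol.  `"relative"` minimizes
#' squared relative residuals (inverse predicted-variance weights),
#' which is the correctly specified estimator when the measurement
#' error is proportional to the mobility — as it is for the synthetic
#' generator — and then yields calibrated standard errors from the same
#' covariance formula.
#'
#' @param records measurement rows for one analyte (internal units).
#' @param seed_model an [analyte_model()] providing starting values
#'   (normally [stepwise_model()] output).
#' @param weights `"none"` or `"relative"`.
#' @param v a [viscosity_model()].
#' @return An object of class `ace_global_fit`: `estimate` and `se`
#'   (named 13-vectors, mobility products in 1e-11 N/V), `cov` (free
#'   parameters), `residuals` (observed - fitted, 1e-11 N/V), `fitted`,
#'   `observed`, `n`, `objective` (residual sum of squares),
#'   `converged`, `niter`, `frozen`, `model` (the fitted
#'   [analyte_model()]), `audit`.
#' @export
fit_global <- function(records, seed_model, weights = c("none", "relative"),
                       v = viscosity_model()) {
  weights <- match.arg(weights)
  stopifnot(inherits(seed_model, "analyte_model"))
  if (length(unique(records$analyte)) != 1)
    stop("fit_global takes the records of a single analyte")
  start <- analyte_params(seed_model)
  free <- rep(TRUE, length(start))
  names(free) <- names(start)
  if (length(unique(records$cCD[records$cCD > 0])) < 2)
    free[c("pK_anion_CD", "lam_anion_CD", "eta_mu_CD",
           "pK_neutral_CD", "lam_neutral_CD")] <- FALSE
  if (length(unique(records$cmCD[records$cmCD > 0])) < 2)
    free[c("pK_anion_mCD", "lam_anion_mCD", "eta_mu_mCD",
           "pK_neutral_mCD", "lam_neutral_mCD")] <- FALSE
  if (length(unique(records$pH)) < 3)
    free[c("pKa0", "lam_a")] <- FALSE
  if (!all(free))
    warning("structurally weak design; frozen at seed values: ",
            paste(names(start)[!free], collapse = ", "))
  y <- .obs_eta_mu(records, v)
  full <- start
  resid_fn <- function(p) {
    full[names(start)[free]] <- p
    pred <- .predict_eta_mu(full, records)
    if (weights == "relative") (pred - y) / pred else pred - y
  }
  fit <- .lm_least_squares(start[free], resid_fn)
  if (!fit$converged)
    warning("global fit did not converge: info ", fit$info, " after ",
            fit$niter, " iterations (seed and trace retained in the result)")
  est <- start
  est[names(start)[free]] <- fit$par
  se <- setNames(rep(NA_real_, length(start)), names(start))
  se[names(start)[free]] <- fit$se
  fitted <- .predict_eta_mu(est, records)
  structure(list(estimate = est, se = se, cov = fit$cov,
                 residuals = y - fitted, fitted = fitted, observed = y,
                 n = length(y), objective = fit$rss,
                 converged = fit$converged, niter = fit$niter,
                 frozen = names(start)[!free],
                 weights = weights,
                 seed = start,
                 model = params_to_analyte(est),
                 audit = list(n_fits = 1L, n_parameters = sum(free))),
            class = "ace_global_fit")
}

#' @export
print.ace_global_fit <- function(x, ...) {
  cat(sprintf("Global fit: %d records, %d free parameters, RSS = %.4g, %s\n",
              x$n, x$audit$n_parameters, x$objective,
              if (x$converged) "converged" else "NOT converged"))
  print(data.frame(estimate = x$estimate, se = x$se), digits = 4)
  invisible(x)
}
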