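#' Capillary geometry and applied voltage
#'
#' @param Lt total capillary length, m.
#' @param Ld inlet-to-detector length, m.
#' @param U applied voltage, V.
#' @return An object of class `capillary_config`.
#' @export
capillary_config <- function(Lt = 0.60, Ld = 0.50, U) {
  if (!(Ld > 0 && Ld < Lt)) stop("need 0 < Ld < Lt")
  if (U <= 0) stop("voltage must be positive")
  structure(list(Lt = Lt, Ld = Ld, U = U), class = "capillary_config")
}

#' Electrophoretic mobility from elution times
#'
#' `mu = Ld * Lt / U * (1 / tX - 1 / t_eof)`, returned as an absolute
#' value (the analytes are anions eluting after the neutral
#' electroosmotic-flow marker, so the signed mobility is negative).
#' Vectorized over times and voltage.
#'
#' @param t_analyte,t_eof elution times of the analyte and of the
#'   neutral marker, s.
#' @param cap a [capillary_config()], or `NULL` if `Lt`, `Ld`, `U` are
#'   given directly.
#' @param Lt,Ld,U geometry (m) and voltage (V) overriding `cap`.
#' @return mobility magnitude, m2 V-1 s-1.
#' @export
#' @examples
#' mobility_from_times(180, 120, Lt = 0.60, Ld = 0.50, U = 2e4)
mobility_from_times <- function(t_analyte, t_eof, cap = NULL,
                                Lt = cap$Lt, Ld = cap$Ld, U = cap$U) {
  if (any(t_analyte <= 0) || any(t_eof <= 0))
    stop("elution times must be positive")
  if (any(U <= 0) || any(Ld <= 0) || any(Lt <= Ld))
    stop("invalid capillary configuration")
  abs(Ld * Lt / U * (1 / t_analyte - 1 / t_eof))
}

#' Viscosity slope from electroosmotic-flow times
#'
#' The electroosmotic-flow time is inversely proportional to the
#' electroosmotic mobility and therefore proportional to the buffer
#' viscosity.  Dividing out the pure-water viscosity, `t_eof /
#' eta0(theta)` is linear in the total cyclodextrin concentration:
#' intercept `a` and slope `a * epsilon`.  The slope ratio estimates
#' `epsilon`; its standard error follows from the delta method on the
#' regression covariance.  Adsorption on the capillary wall lengthens
#' individual EOF times, so the residuals of this regression are
#' expected to be positively skewed; their skewness is reported as a
#' diagnostic.
#'
#' @param records data frame with columns `t_eof` (s), `theta` (C) and
#'   `c_total` (mol/L) — or `cCD`/`cmCD`, summed internally.  Replicates
#'   enter individually.  If a voltage column `U` is present the EOF
#'   times are voltage-normalized first (`t_eof` scales as `1/U`), so
#'   runs acquired at different voltages can be pooled.
#' @return A list of class `epsilon_fit`: `epsilon`, `se_epsilon`,
#'   `intercept`, `r_squared`, `residual_skewness`, `n`, and the `lm`
#'   fit object.
#' @export
fit_epsilon <- function(records) {
  stopifnot(is.data.frame(records), "t_eof" %in% names(records),
            "theta" %in% names(records))
  c_total <- if ("c_total" %in% names(records)) records$c_total
             else records$cCD + records$cmCD
  if (length(unique(c_total)) < 3)
    stop("need at least 3 distinct ligand concentrations to estimate epsilon")
  y <- records$t_eof / water_viscosity(records$theta)
  if ("U" %in% names(records)) y <- y * records$U / median(records$U)
  fit <- lm(y ~ c_total)
  cf <- coef(fit)
  if (!is.finite(cf[2]) || cf[1] == 0) stop("rank-deficient design for epsilon fit")
  V <- suppressWarnings(vcov(fit))
  eps <- unname(cf[2] / cf[1])
  # delta method for a ratio of coefficients
  g <- c(-cf[2] / cf[1]^2, 1 / cf[1])
  se <- sqrt(drop(t(g) %*% V %*% g))
  res <- stats::residuals(fit)
  structure(list(epsilon = eps, se_epsilon = se, intercept = unname(cf[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 residual_skewness = .skewness(res),
                 n = length(y), lm_fit = fit),
            class = "epsilon_fit")
}

#' @export
print.epsilon_fit <- function(x, ...) {
  cat(sprintf("epsilon = %.3f +/- %.3f M-1  (n = %d, R2 = %.3f, residual skewness %.2f)\n",
              x$epsilon, x$se_epsilon, x$n, x$r_squared, x$residual_skewness))
  invisible(x)
}

# CSV schema used for measurement exchange (one row per analyte per run)
.ace_csv_columns <- c("analyte", "buffer_id", "pH", "temperature_C",
                      "cCD_mM", "cmCD_mM", "voltage_kV", "Lt_cm", "Ld_cm",
                      "t_eof_s", "t_analyte_s", "replicate")

#' Read a measurement table from CSV
#'
#' Expected columns: `analyte`, `buffer_id`, `pH`, `temperature_C`,
#' `cCD_mM`, `cmCD_mM`, `voltage_kV`, `Lt_cm`, `Ld_cm`, `t_eof_s`,
#' `t_analyte_s`, `replicate`; comma-separated, dot decimal, header row
#' mandatory, `#`-prefixed provenance lines ignored.  Mobilities are
#' computed from the times via [mobility_from_times()]; alternatively a
#' `mobility_1e9` column (units 1e-9 m2 V-1 s-1) may replace the two
#' time columns.
#'
#' @param path file path.
#' @return data frame in internal units: `analyte`, `buffer_id`, `pH`,
#'   `theta` (C), `cCD`, `cmCD` (mol/L), `U` (V), `Lt`, `Ld` (m),
#'   `t_eof`, `t_analyte` (s, possibly `NA`), `replicate`, `mobility`
#'   (m2 V-1 s-1, absolute value).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  has_times <- all(c("t_eof_s", "t_analyte_s") %in% names(d))
  needed <- setdiff(.ace_csv_columns, c("t_eof_s", "t_analyte_s"))
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  if (!has_times && !("mobility_1e9" %in% names(d)))
    stop("need either t_eof_s/t_analyte_s or mobility_1e9 columns")
  out <- data.frame(
    analyte = as.character(d$analyte),
    buffer_id = as.character(d$buffer_id),
    pH = as.numeric(d$pH),
    theta = as.numeric(d$temperature_C),
    cCD = as.numeric(d$cCD_mM) * 1e-3,
    cmCD = as.numeric(d$cmCD_mM) * 1e-3,
    U = as.numeric(d$voltage_kV) * 1e3,
    Lt = as.numeric(d$Lt_cm) * 1e-2,
    Ld = as.numeric(d$Ld_cm) * 1e-2,
    replicate = as.integer(d$replicate),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(out$pH) | out$pH <= 0 | out$pH >= 14 |
                 out$cCD < 0 | out$cmCD < 0 | out$U <= 0 | out$Ld >= out$Lt)
  if (length(bad))
    stop("invalid field values at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  if (has_times) {
    out$t_eof <- as.numeric(d$t_eof_s)
    out$t_analyte <- as.numeric(d$t_analyte_s)
    if (any(out$t_eof <= 0) || any(out$t_analyte <= 0))
      stop("elution times must be positive")
    out$mobility <- mobility_from_times(out$t_analyte, out$t_eof,
                                        Lt = out$Lt, Ld = out$Ld, U = out$U)
  } else {
    out$t_eof <- NA_real_
    out$t_analyte <- NA_real_
    out$mobility <- abs(as.numeric(d$mobility_1e9)) * 1e-9
  }
  out
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]: converts internal units back to the
#' file schema (mM, kV, cm).  An optional provenance header is written
#' as `#`-prefixed lines.
#'
#' @param records internal-unit data frame (see [read_measurements()]).
#' @param path output file path.
#' @param header optional character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, header = NULL) {
  d <- data.frame(
    analyte = records$analyte,
    buffer_id = records$buffer_id,
    pH = records$pH,
    temperature_C = records$theta,
    cCD_mM = records$cCD * 1e3,
    cmCD_mM = records$cmCD * 1e3,
    voltage_kV = records$U / 1e3,
    Lt_cm = records$Lt * 1e2,
    Ld_cm = records$Ld * 1e2,
    t_eof_s = records$t_eof,
    t_analyte_s = records$t_analyte,
    replicate = records$replicate
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}

# sample skewness and excess kurtosis (moment estimators; normal -> 0, 0)
.skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

.excess_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}
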