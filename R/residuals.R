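#' Core residual summary
#'
#' Correlation and moment diagnostics of a fit: R-squared as the squared
#' Pearson correlation of observed versus fitted values, residual
#' standard deviation, the same expressed as a fraction of the mean
#' absolute observation, and residual skewness / excess kurtosis
#' (normal = 0 convention).
#'
#' @param observed,fitted numeric vectors of equal length (>= 10).
#' @return A list of class `residual_report` with `r_squared`,
#'   `residual_sd`, `residual_sd_fraction`, `skewness`,
#'   `excess_kurtosis`, `n`, `degenerate` (TRUE when either vector is
#'   constant, in which case `r_squared` is `NA`).
#' @export
residual_summary <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stop("length mismatch")
  if (length(observed) < 10) stop("need >= 10 points for residual diagnostics")
  res <- observed - fitted
  degenerate <- sd(observed) == 0 || sd(fitted) == 0
  r2 <- if (degenerate) NA_real_ else cor(observed, fitted)^2
  structure(list(r_squared = r2,
                 residual_sd = sd(res),
                 residual_sd_fraction = sd(res) / mean(abs(observed)),
                 skewness = .skewness(res),
                 excess_kurtosis = .excess_kurtosis(res),
                 n = length(res), degenerate = degenerate),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("n = %d  R2 = %.4f  sd = %.4g (%.2f%% of mean |obs|)\n",
              x$n, x$r_squared, x$residual_sd, 100 * x$residual_sd_fraction))
  cat(sprintf("skewness = %.3f  excess kurtosis = %.3f\n",
              x$skewness, x$excess_kurtosis))
  invisible(x)
}

# negative log-likelihood of a location-scale Student-t sample
.t_nll <- function(par, x) {
  loc <- par[1]
  s <- exp(par[2])
  nu <- exp(par[3])
  -sum(dt((x - loc) / s, df = nu, log = TRUE) - log(s))
}

#' Fit normal and Student-t error models to residuals
#'
#' Maximum-likelihood fits of a normal and a location-scale Student-t
#' distribution, each followed by a Kolmogorov-Smirnov test of the
#' sample against the fitted distribution.  The distribution parameters
#' are estimated from the same sample the KS test is applied to, so the
#' reported p-values are optimistic (biased upward); the result carries
#' a `ks_caveat` flag recording this.  A heavy-tailed sample yields a
#' small fitted `nu` and a rejected normal hypothesis.
#'
#' @param residuals numeric vector, n >= 20.
#' @return A list of class `residual_dist_fit` with elements `normal`
#'   (`loc`, `scale`, `loglik`, `ks_statistic`, `ks_p`), `t` (`loc`,
#'   `scale`, `nu`, `loglik`, `ks_statistic`, `ks_p`), `skewness`,
#'   `excess_kurtosis`, `converged`, `ks_caveat`.
#' @export
fit_residual_distributions <- function(residuals) {
  x <- residuals[is.finite(residuals)]
  if (length(x) < 20) stop("need >= 20 residuals to fit error distributions")
  loc_n <- mean(x)
  scale_n <- sqrt(mean((x - loc_n)^2))  # ML, not the n-1 estimator
  ll_n <- sum(dnorm(x, loc_n, scale_n, log = TRUE))
  ks_n <- suppressWarnings(ks.test(x, "pnorm", loc_n, scale_n))
  s0 <- mad(x)
  if (s0 == 0) s0 <- scale_n
  start <- c(median(x), log(s0), log(5))
  opt <- optim(start, .t_nll, x = x, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  # polish: restart once from the optimum (Nelder-Mead can stall)
  opt <- optim(opt$par, .t_nll, x = x, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  conv <- opt$convergence == 0
  if (!conv) warning("t-distribution ML fit did not converge")
  loc_t <- opt$par[1]
  scale_t <- exp(opt$par[2])
  nu <- exp(opt$par[3])
  ks_t <- suppressWarnings(
    ks.test(x, function(q) pt((q - loc_t) / scale_t, df = nu)))
  structure(list(
    normal = list(loc = loc_n, scale = scale_n, loglik = ll_n,
                  ks_statistic = unname(ks_n$statistic), ks_p = ks_n$p.value),
    t = list(loc = loc_t, scale = scale_t, nu = nu, loglik = -opt$value,
             ks_statistic = unname(ks_t$statistic), ks_p = ks_t$p.value),
    skewness = .skewness(x), excess_kurtosis = .excess_kurtosis(x),
    converged = conv,
    ks_caveat = "KS p-values computed with parameters estimated from the same sample"),
    class = "residual_dist_fit")
}

#' @export
print.residual_dist_fit <- function(x, ...) {
  cat(sprintf("normal: loc %.3g scale %.3g  logL %.1f  KS p = %.3g\n",
              x$normal$loc, x$normal$scale, x$normal$loglik, x$normal$ks_p))
  cat(sprintf("t:      loc %.3g scale %.3g nu %.2f  logL %.1f  KS p = %.3g\n",
              x$t$loc, x$t$scale, x$t$nu, x$t$loglik, x$t$ks_p))
  cat(sprintf("skewness %.3f, excess kurtosis %.3f  (%s)\n",
              x$skewness, x$excess_kurtosis, x$ks_caveat))
  invisible(x)
}

#' Residual diagnostic plots
#'
#' Two-panel figure: observed versus fitted mobility-viscosity products,
#' and the residual histogram overlaid with the fitted normal and
#' Student-t densities.
#'
#' @param observed,fitted numeric vectors.
#' @param dist optional [fit_residual_distributions()] result (computed
#'   if omitted).
#' @param file optional output path (pdf or png by extension); plots to
#'   the active device when `NULL`.
#' @return the `residual_dist_fit`, invisibly.
#' @export
plot_residual_diagnostics <- function(observed, fitted, dist = NULL,
                                      file = NULL) {
  res <- observed - fitted
  if (is.null(dist)) dist <- fit_residual_distributions(res)
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 1400, 700, res = 150)
    else grDevices::pdf(file, width = 9, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  plot(fitted, observed, pch = 16, cex = 0.5,
       xlab = "fitted", ylab = "observed", main = "correlation")
  graphics::abline(0, 1, col = "grey50")
  h <- graphics::hist(res, breaks = 40, freq = FALSE,
                      main = "residual distribution", xlab = "residual")
  xx <- seq(min(h$breaks), max(h$breaks), length.out = 400)
  graphics::lines(xx, dnorm(xx, dist$normal$loc, dist$normal$scale),
                  col = "steelblue", lwd = 2)
  graphics::lines(xx, dt((xx - dist$t$loc) / dist$t$scale, dist$t$nu) /
                    dist$t$scale, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("normal", "Student-t"), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(dist)
}
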