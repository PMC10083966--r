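## Configuration-driven entry points tying the pipeline together.  Each
## ace_* command takes a run configuration (YAML file or list), writes
## delimited report tables with a provenance header (package version,
## seed, config checksum) and returns its result invisibly, so the same
## surface serves interactive use and scripted runs.

#' Read and normalize a run configuration
#'
#' @param config path to a YAML file, or a named list.  Recognized
#'   top-level fields: `seed` (mandatory), `output_dir`, `input`,
#'   `procedure` (`"stepwise"`, `"global"` or `"both"`), `noise`,
#'   `design`, `truth`, `epsilon`, `eof_mobility`, `n_sim`, `plots`.
#' @return a validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  if (is.null(config$seed)) stop("config must carry a seed")
  config$seed <- as.integer(config$seed)
  config$output_dir <- config$output_dir %||% "."
  config$procedure <- match.arg(config$procedure %||% "both",
                                c("both", "stepwise", "global"))
  structure(config, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# polynomial rolling checksum of the canonicalized config (provenance
# tag only, not cryptographic)
.config_checksum <- function(config) {
  s <- utf8ToInt(paste(deparse(config[order(names(config))]), collapse = "\n"))
  h <- 0
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenance <- function(config) {
  # the checksum covers the scientific configuration, not where the
  # outputs land: identical runs into different directories must
  # produce identical files
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  c(sprintf("acebind %s", as.character(packageVersion("acebind"))),
    sprintf("seed %d", config$seed),
    sprintf("config %s", .config_checksum(cfg)))
}

.write_report <- function(d, path, config, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .provenance(config)), con)
  if (!is.null(units)) writeLines(paste0("# units: ", units), con)
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}

.truth_from_config <- function(config) {
  if (is.null(config$truth)) return(default_ground_truth())
  lapply(config$truth, function(p) params_to_analyte(unlist(p)))
}

.noise_from_config <- function(config) {
  nm <- config$noise %||% list()
  do.call(noise_model, modifyList(list(seed = config$seed), nm))
}

.design_from_config <- function(config) {
  d <- config$design %||% list()
  if (!is.null(d$ph_levels)) d$ph_levels <- unlist(d$ph_levels)
  do.call(design_grid, d)
}

#' Simulate a measurement dataset and write it to CSV
#'
#' Generates mobilities and elution times from the configured ground
#' truth, design and noise model and writes them in the measurement CSV
#' schema with a provenance header.  Idempotent for a fixed
#' configuration and seed.
#'
#' @param config a [run_config()] (or path / list); uses fields `seed`,
#'   `output_dir`, `truth`, `design`, `noise`, `eof_mobility`,
#'   `epsilon`.
#' @return the records data frame, invisibly.
#' @export
ace_simulate <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  noise <- .noise_from_config(config)
  v <- viscosity_model(config$epsilon %||% 8.2)
  recs <- simulate_mobilities(.truth_from_config(config),
                              .design_from_config(config),
                              noise, v, seed = config$seed)
  recs <- simulate_times(recs, config$eof_mobility %||% 6e-8, noise, v,
                         seed = config$seed + 1L)
  path <- file.path(config$output_dir, "measurements.csv")
  write_measurements(recs, path, header = .provenance(config))
  invisible(recs)
}

#' Fit a measurement dataset and write parameter reports
#'
#' Reads the measurement CSV, runs the stepwise and/or global procedure,
#' and writes `parameters.csv` (long format: procedure, analyte,
#' parameter, estimate, se — mobility products in 1e-11 N/V, pK and
#' lambda on their natural scales) plus `fit_audit.txt` recording the
#' number of independent fits and fitted parameters per procedure.
#'
#' @param config a [run_config()]; uses `input` (CSV path), `procedure`,
#'   `epsilon`, `output_dir`, `seed`.
#' @return list with elements `stepwise` (a `stepwise_results`) and
#'   `global` (named list of `ace_global_fit`), invisibly; absent
#'   procedures are `NULL`.
#' @export
ace_fit <- function(config) {
  config <- run_config(config)
  if (is.null(config$input)) stop("config$input (measurement CSV) is required")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- read_measurements(config$input)
  v <- viscosity_model(config$epsilon %||% 8.2)
  sw <- NULL
  gl <- NULL
  rows <- list()
  audit <- character(0)
  if (config$procedure %in% c("both", "stepwise", "global")) {
    sw <- fit_stepwise(recs, v)
    audit <- c(audit, sprintf("stepwise: %d independent fits, %d parameters",
                              sw$audit$n_fits, sw$audit$n_parameters))
    if (config$procedure %in% c("both", "stepwise")) {
      for (a in unique(sw$step1$analyte)) {
        p <- stepwise_params(sw, a)
        rows[[length(rows) + 1L]] <- data.frame(
          procedure = "stepwise", analyte = a,
          parameter = names(p$estimate),
          estimate = unname(p$estimate), se = unname(p$se))
      }
    }
  }
  if (config$procedure %in% c("both", "global")) {
    analytes <- unique(recs$analyte)
    gl <- lapply(setNames(analytes, analytes), function(a)
      fit_global(recs[recs$analyte == a, ], stepwise_model(sw, a), v = v))
    audit <- c(audit, sprintf("global: %d independent fits, %d parameters",
                              length(gl), sum(vapply(gl, function(g)
                                g$audit$n_parameters, 0L))))
    for (a in names(gl)) {
      rows[[length(rows) + 1L]] <- data.frame(
        procedure = "global", analyte = a,
        parameter = names(gl[[a]]$estimate),
        estimate = unname(gl[[a]]$estimate), se = unname(gl[[a]]$se))
    }
  }
  params <- do.call(rbind, rows)
  .write_report(params, file.path(config$output_dir, "parameters.csv"), config,
                units = "eta_mu in 1e-11 N/V; lam in 1/K")
  writeLines(c(paste0("# ", .provenance(config)), audit),
             file.path(config$output_dir, "fit_audit.txt"))
  invisible(list(stepwise = if (config$procedure != "global") sw else NULL,
                 global = gl, parameters = params))
}

#' pK parameter table of all equilibria from a global fit
#'
#' Expands one analyte's 13-parameter global fit into the per-reaction
#' (pK0, lambda) table: anion and neutral binding for each ligand, the
#' free acid, and the complexed acids composed through the
#' thermodynamic cycle.  Standard errors and the pK0-lambda covariances
#' use the full fit covariance matrix.
#'
#' @param fit an `ace_global_fit`.
#' @param analyte analyte id used in the reaction labels.
#' @return data frame with columns `reaction`, `pK0`, `lam`, `se_pK0`,
#'   `se_lam`, `cov_pK0_lam`, suitable for [thermo_table()].
#' @export
global_pk_table <- function(fit, analyte = "X") {
  stopifnot(inherits(fit, "ace_global_fit"))
  C <- matrix(0, 13, 13, dimnames = list(names(fit$estimate), names(fit$estimate)))
  free <- setdiff(names(fit$estimate), fit$frozen)
  C[free, free] <- fit$cov[free, free]
  est <- fit$estimate
  lincomb <- function(w) {
    # w: named weights over the 13 parameters; returns value, se
    v <- sum(w * est[names(w)])
    se <- sqrt(drop(t(w) %*% C[names(w), names(w)] %*% w))
    c(v, se)
  }
  covof <- function(wa, wb) {
    drop(t(wa) %*% C[names(wa), names(wb)] %*% wb)
  }
  rows <- list()
  add <- function(reaction, w_pk, w_lam) {
    pk <- lincomb(w_pk)
    lam <- lincomb(w_lam)
    rows[[length(rows) + 1L]] <<- data.frame(
      reaction = reaction, pK0 = pk[1], lam = lam[1],
      se_pK0 = pk[2], se_lam = lam[2],
      cov_pK0_lam = covof(w_pk, w_lam))
  }
  one <- function(nm) setNames(1, nm)
  for (lig in c("CD", "mCD")) {
    add(sprintf("%s-.%s", analyte, lig),
        one(paste0("pK_anion_", lig)), one(paste0("lam_anion_", lig)))
    add(sprintf("%sH.%s", analyte, lig),
        one(paste0("pK_neutral_", lig)), one(paste0("lam_neutral_", lig)))
  }
  add(analyte, one("pKa0"), one("lam_a"))
  for (lig in c("CD", "mCD")) {
    w_pk <- setNames(c(1, 1, -1), c("pKa0", paste0("pK_anion_", lig),
                                    paste0("pK_neutral_", lig)))
    w_lam <- setNames(c(1, 1, -1), c("lam_a", paste0("lam_anion_", lig),
                                     paste0("lam_neutral_", lig)))
    add(sprintf("%s.%s", analyte, lig), w_pk, w_lam)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Thermodynamic report
#'
#' Builds the thermodynamic table (pK(T0), dG0, dH0, dS0 with standard
#' errors, contribution fractions) for every equilibrium.  Input is
#' either the in-memory result of [ace_fit()] (full covariances) or a
#' `parameters.csv`-style file written by it (pK0-lambda covariances
#' taken as zero, which only affects the dS0 standard errors).
#'
#' @param config a [run_config()]; uses `input` (parameters.csv path)
#'   unless `fits` is given, plus `output_dir`, `seed`.
#' @param fits optional named list of `ace_global_fit` objects.
#' @return the thermodynamic table, invisibly.
#' @export
ace_thermo <- function(config, fits = NULL) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fits)) {
    if (is.null(config$input)) stop("config$input (parameters.csv) is required")
    pars <- read.csv(config$input, comment.char = "#", stringsAsFactors = FALSE)
    pars <- pars[pars$procedure == "global", ]
    if (nrow(pars) == 0) stop("no global-procedure rows in ", config$input)
    pk_table <- do.call(rbind, lapply(split(pars, pars$analyte),
                                      .pk_table_from_params))
  } else {
    pk_table <- do.call(rbind, lapply(names(fits), function(a)
      global_pk_table(fits[[a]], a)))
  }
  tab <- thermo_table(pk_table)
  .write_report(tab, file.path(config$output_dir, "thermodynamics.csv"), config,
                units = "dG0, dH0 in kJ/mol at T0 = 299 K; dS0 in J/K/mol; xS, xH, rSH dimensionless")
  invisible(tab)
}

# reaction pK table from a long (parameter, estimate, se) frame, cov = 0
.pk_table_from_params <- function(d) {
  a <- d$analyte[1]
  g <- function(p, col = "estimate") d[[col]][d$parameter == p]
  tlp <- function(pre) temp_linear_pk(g(paste0("pK_", pre)), g(paste0("lam_", pre)),
                                      g(paste0("pK_", pre), "se"),
                                      g(paste0("lam_", pre), "se"))
  acid <- temp_linear_pk(g("pKa0"), g("lam_a"), g("pKa0", "se"), g("lam_a", "se"))
  rows <- list()
  for (lig in c("CD", "mCD")) {
    an <- tlp(paste0("anion_", lig))
    ne <- tlp(paste0("neutral_", lig))
    cx <- complex_acidity(acid, an, ne)
    rows[[length(rows) + 1L]] <- data.frame(
      reaction = c(sprintf("%s-.%s", a, lig), sprintf("%sH.%s", a, lig),
                   sprintf("%s.%s", a, lig)),
      pK0 = c(an$pK0, ne$pK0, cx$pK0), lam = c(an$lam, ne$lam, cx$lam),
      se_pK0 = c(an$se_pK0, ne$se_pK0, cx$se_pK0),
      se_lam = c(an$se_lam, ne$se_lam, cx$se_lam),
      cov_pK0_lam = 0)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    reaction = a, pK0 = acid$pK0, lam = acid$lam,
    se_pK0 = acid$se_pK0, se_lam = acid$se_lam, cov_pK0_lam = 0)
  do.call(rbind, rows)
}

#' Residual diagnostics report
#'
#' Fits the configured procedure(s) to the input dataset and writes the
#' residual summary and error-model comparison for each, plus optional
#' diagnostic figures.
#'
#' @param config a [run_config()]; uses `input`, `procedure`,
#'   `epsilon`, `output_dir`, `plots` (logical; figures are written as
#'   `diagnostics_<procedure>.pdf`), `seed`.
#' @return data frame of diagnostics, invisibly.
#' @export
ace_diagnose <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- ace_fit(config)
  recs <- read_measurements(config$input)
  v <- viscosity_model(config$epsilon %||% 8.2)
  out <- list()
  collect <- function(procedure, observed, fitted) {
    rs <- residual_summary(observed, fitted)
    fd <- fit_residual_distributions(observed - fitted)
    if (isTRUE(config$plots))
      plot_residual_diagnostics(observed, fitted, fd,
                                file.path(config$output_dir,
                                          sprintf("diagnostics_%s.pdf", procedure)))
    data.frame(procedure = procedure, n = rs$n, r_squared = rs$r_squared,
               residual_sd = rs$residual_sd,
               residual_sd_fraction = rs$residual_sd_fraction,
               skewness = rs$skewness, excess_kurtosis = rs$excess_kurtosis,
               normal_ks_p = fd$normal$ks_p, t_nu = fd$t$nu,
               t_ks_p = fd$t$ks_p)
  }
  if (!is.null(fits$global)) {
    obs <- unlist(lapply(fits$global, `[[`, "observed"))
    fit <- unlist(lapply(fits$global, `[[`, "fitted"))
    out[[length(out) + 1L]] <- collect("global", obs, fit)
  }
  if (!is.null(fits$stepwise) && config$procedure %in% c("both", "stepwise")) {
    sw <- fits$stepwise
    obs <- .obs_eta_mu(recs, v)
    pred <- numeric(nrow(recs))
    for (a in unique(recs$analyte)) {
      idx <- recs$analyte == a
      pred[idx] <- mobility_product(stepwise_model(sw, a), recs[idx, ]) * 1e11
    }
    out[[length(out) + 1L]] <- collect("stepwise", obs, pred)
  }
  tab <- do.call(rbind, out)
  .write_report(tab, file.path(config$output_dir, "diagnostics.csv"), config,
                units = "residuals on the 1e-11 N/V eta-mu scale")
  invisible(tab)
}

#' Parameter-recovery report
#'
#' Runs [parameter_recovery()] under the configured truth, design and
#' noise and writes the per-parameter bias / RMSE / coverage table.
#'
#' @param config a [run_config()]; uses `seed`, `n_sim` (default 10),
#'   `procedure` (default `"global"`), `truth`, `design`, `noise`,
#'   `epsilon`, `output_dir`.
#' @return the `recovery_report`, invisibly.
#' @export
ace_recover <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  proc <- if (config$procedure %in% c("stepwise", "global")) config$procedure else "global"
  rep <- parameter_recovery(.truth_from_config(config),
                            .design_from_config(config),
                            .noise_from_config(config),
                            n_sim = config$n_sim %||% 10L,
                            procedure = proc, seed = config$seed,
                            v = viscosity_model(config$epsilon %||% 8.2))
  .write_report(rep$summary, file.path(config$output_dir, "recovery.csv"),
                config, units = "eta_mu parameters in 1e-11 N/V; pK and lam natural scales")
  invisible(rep)
}
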