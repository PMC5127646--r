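# Unit conventions, centralized: concentrations uM, volumes ul, heats ucal,
# enthalpies kcal/mol. 1 kcal/mol * 1 uM * 1 ul = 1e-3 ucal.
UCAL_PER_KCALMOL_UM_UL <- 1e-3

#' Construct an ITC experiment
#'
#' Container for a perfusion-cell ITC titration: the cell holds the protein,
#' the syringe the titrant, and each injection displaces its own volume from
#' the (overfilled) cell.
#'
#' @param cell_conc initial protein concentration in the cell (uM).
#' @param syringe_conc titrant concentration in the syringe (uM), > 0.
#' @param cell_volume active cell volume (ul); 200 ul matches the
#'   small-volume calorimeter class used for these titrations.
#' @param injection_volumes per-injection volumes (ul), all > 0.
#' @param heats observed or simulated per-injection heats (ucal), one per
#'   injection, or `NULL` for a design without data.
#' @param temperature cell temperature (degrees C).
#' @return An object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_conc, syringe_conc, cell_volume = 200,
                           injection_volumes = c(0.4, rep(1, 38)),
                           heats = NULL, temperature = 24) {
  if (syringe_conc <= 0) stop("syringe_conc must be > 0", call. = FALSE)
  if (cell_conc <= 0) stop("cell_conc must be > 0", call. = FALSE)
  if (any(injection_volumes <= 0))
    stop("injection volumes must be > 0", call. = FALSE)
  if (!is.null(heats) && length(heats) != length(injection_volumes))
    stop("need one heat per injection", call. = FALSE)
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume,
                 injection_volumes = as.numeric(injection_volumes),
                 heats = if (is.null(heats)) NULL else as.numeric(heats),
                 temperature = temperature),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf("ITC experiment: cell %.4g uM, syringe %.4g uM, V0 %.4g ul, %d injections (%.1f ul total), %.1f C\n",
              x$cell_conc, x$syringe_conc, x$cell_volume,
              length(x$injection_volumes), sum(x$injection_volumes),
              x$temperature))
  if (!is.null(x$heats))
    cat(sprintf("  heats: %.3g .. %.3g ucal\n",
                x$heats[1], x$heats[length(x$heats)]))
  invisible(x)
}

#' Cell concentrations along an ITC titration
#'
#' Standard perfusion-displacement dilution: each injection pushes its own
#' volume out of the fixed-volume cell, so after a cumulative injected
#' volume \eqn{v}, protein and previously injected titrant are diluted while
#' fresh titrant is delivered at syringe concentration:
#' \deqn{P_i = P_0 \frac{1 - v_i/2V_0}{1 + v_i/2V_0}, \qquad
#'       L_i = L_{syr} \frac{v_i/V_0}{1 + v_i/2V_0}.}
#'
#' @param expt an [itc_experiment()].
#' @return `data.frame` with one row per injection: `injection`,
#'   `volume_ul`, `protein_conc`, `ligand_conc`, `molar_ratio` (all
#'   concentrations uM, evaluated after the injection).
#' @export
itc_concentrations <- function(expt) {
  v <- cumsum(expt$injection_volumes)
  V0 <- expt$cell_volume
  P <- expt$cell_conc * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
  L <- expt$syringe_conc * (v / V0) / (1 + v / (2 * V0))
  data.frame(injection = seq_along(v), volume_ul = expt$injection_volumes,
             protein_conc = P, ligand_conc = L, molar_ratio = L / P)
}

# Cumulative heat content of the cell (ucal) after each injection under the
# one-site model with stoichiometry n: Q_i = dH * V0 * [PL]_i where
# [PL] = n * P * f_bound(nP, L, K).
itc_cumulative_heat <- function(expt, kd, dh, n) {
  conc <- itc_concentrations(expt)
  sites <- n * conc$protein_conc
  pl <- sites * fraction_bound(sites, conc$ligand_conc, kd)
  dh * expt$cell_volume * pl * UCAL_PER_KCALMOL_UM_UL
}

# Model per-injection heats: finite difference of Q with the displacement
# correction for heat carried out of the active volume.
itc_model_heats <- function(expt, kd, dh, n, q_dilution = 0) {
  Q <- itc_cumulative_heat(expt, kd, dh, n)
  Qprev <- c(0, Q[-length(Q)])
  dV <- expt$injection_volumes
  Q - Qprev + (dV / expt$cell_volume) * (Q + Qprev) / 2 + q_dilution
}

#' Simulate one-site ITC injection heats
#'
#' Generates the per-injection heat series for a 1:1 binding reaction in a
#' perfusion calorimeter. The cumulative heat after injection i is
#' \eqn{Q_i = \Delta H \, V_0 \, [PL]_i} with the complex concentration from
#' the exact quadratic isotherm ([fraction_bound()]) on the
#' dilution-corrected concentrations ([itc_concentrations()]); the observed
#' heat of injection i is
#' \deqn{q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2},}
#' the last term compensating for heat displaced out of the active volume.
#'
#' @param kd dissociation constant (uM).
#' @param dh binding enthalpy (kcal/mol).
#' @param n stoichiometry (sites per protein).
#' @param design an [itc_experiment()] (its `heats` are ignored).
#' @param q_dilution constant heat-of-dilution offset per injection (ucal).
#' @param noise_sd Gaussian read-noise SD (ucal) added to each heat.
#' @param seed optional seed used (locally) when `noise_sd > 0`.
#' @return The design [itc_experiment()] with `heats` filled in and the
#'   ground-truth parameters attached as attribute `truth`.
#' @export
simulate_itc <- function(kd, dh, n = 1, design = itc_experiment(100, 1000),
                         q_dilution = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(design, "itc_experiment"))
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  q <- itc_model_heats(design, kd, dh, n, q_dilution)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    q <- q + stats::rnorm(length(q), 0, noise_sd)
  }
  out <- design
  out$heats <- q
  attr(out, "truth") <- list(kd = kd, dh = dh, n = n,
                             q_dilution = q_dilution, noise_sd = noise_sd)
  out
}

#' Wiseman c-value of an ITC design
#'
#' `c = n * P_cell / K_D`; below about 1 the isotherm loses its sigmoidal
#' shape and the stoichiometry is poorly identifiable (the usual remedy,
#' applied here by default in [fit_itc()], is to fix n).
#'
#' @param expt an [itc_experiment()].
#' @param kd dissociation constant (uM).
#' @param n stoichiometry.
#' @return The dimensionless c-value.
#' @export
itc_c_value <- function(expt, kd, n = 1) n * expt$cell_conc / kd

#' Fit the one-site binding model to ITC heats
#'
#' Least-squares fit of the perfusion one-site model (see [simulate_itc()])
#' for \eqn{K_D}, \eqn{\Delta H} and optionally the stoichiometry n and a
#' constant heat-of-dilution baseline. Optimization is multi-start
#' Levenberg-Marquardt over a deterministic grid of log-spaced \eqn{K_D}
#' starting values, so noiseless fits are exactly reproducible. The small
#' pre-injection (first injection) is excluded from the residuals by
#' default, as its heat is corrupted by diffusion from the syringe tip
#' during equilibration. A warning is issued when the Wiseman c-value at the
#' fitted \eqn{K_D} is below 1 while n is being fit.
#'
#' @param expt an [itc_experiment()] with heats.
#' @param fix names of parameters to hold fixed: subset of
#'   `c("n", "baseline")`; both fixed by default (n at `n_value`,
#'   baseline at 0), the regime appropriate for low-c peptide titrations.
#' @param n_value value of n when fixed.
#' @param exclude_first exclude the pre-injection from the residuals.
#' @param kd_starts starting grid for K_D (uM).
#' @return Object of class `itc_fit`: estimates `kd`, `dh`, `n`, `baseline`,
#'   standard errors, `converged`, `low_c`, `fixed`, residuals and the data.
#' @export
fit_itc <- function(expt, fix = c("n", "baseline"), n_value = 1,
                    exclude_first = TRUE,
                    kd_starts = 10^seq(0, 4, by = 0.5)) {
  stopifnot(inherits(expt, "itc_experiment"))
  if (is.null(expt$heats)) stop("experiment has no heats to fit", call. = FALSE)
  keep <- seq_along(expt$heats)
  if (exclude_first) keep <- keep[-1]
  if (length(keep) < 10)
    stop("need at least 10 informative injections", call. = FALSE)
  q_obs <- expt$heats

  fit_n <- !("n" %in% fix)
  fit_bl <- !("baseline" %in% fix)

  if (max(abs(q_obs[keep])) < 1e-9) {
    # No measurable heat: dH ~ 0 and K_D carries no information.
    return(structure(list(kd = NA_real_, dh = 0, n = n_value, baseline = 0,
                          se = c(kd = NA_real_, dh = NA_real_),
                          converged = FALSE, low_c = NA,
                          fixed = fix, expt = expt,
                          residuals = q_obs * 0, fitted = q_obs * 0,
                          residual_norm = 0,
                          message = "all heats ~ 0: K_D not identifiable"),
                     class = "itc_fit"))
  }

  dh0 <- sum(q_obs[keep]) /
    (expt$cell_volume * expt$cell_conc * UCAL_PER_KCALMOL_UM_UL)

  resid_fun <- function(par) {
    kd <- exp(par[["log_kd"]])
    dh <- par[["dh"]]
    n <- if (fit_n) exp(par[["log_n"]]) else n_value
    bl <- if (fit_bl) par[["baseline"]] else 0
    (itc_model_heats(expt, kd, dh, n, bl) - q_obs)[keep]
  }

  best <- NULL
  for (kd0 in kd_starts) {
    par0 <- c(log_kd = log(kd0), dh = dh0)
    if (fit_n) par0 <- c(par0, log_n = 0)
    if (fit_bl) par0 <- c(par0, baseline = 0)
    res <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("ITC fit failed from every starting point", call. = FALSE)

  par <- best$par
  kd <- exp(par[["log_kd"]])
  dh <- par[["dh"]]
  n <- if (fit_n) exp(par[["log_n"]]) else n_value
  bl <- if (fit_bl) par[["baseline"]] else 0

  covm <- tryCatch(vcov(best), error = function(e) NULL)
  se <- c(kd = NA_real_, dh = NA_real_, n = NA_real_, baseline = NA_real_)
  if (!is.null(covm)) {
    se["kd"] <- sqrt(covm["log_kd", "log_kd"]) * kd      # delta method
    se["dh"] <- sqrt(covm["dh", "dh"])
    if (fit_n) se["n"] <- sqrt(covm["log_n", "log_n"]) * n
    if (fit_bl) se["baseline"] <- sqrt(covm["baseline", "baseline"])
  }

  fitted <- itc_model_heats(expt, kd, dh, n, bl)
  at_bound <- kd < 1.01 * min(kd_starts) / 1e3 || kd > 0.99 * max(kd_starts) * 1e3
  converged <- best$info %in% 1:4 && !at_bound
  low_c <- itc_c_value(expt, kd, n) < 1
  if (low_c && fit_n)
    warning(sprintf("low c-value (c = %.2f < 1): stoichiometry poorly identifiable; consider fixing n",
                    itc_c_value(expt, kd, n)), call. = FALSE)

  structure(list(kd = kd, dh = dh, n = n, baseline = bl, se = se,
                 converged = converged, low_c = low_c,
                 fixed = fix, expt = expt,
                 residuals = q_obs - fitted, fitted = fitted,
                 excluded = if (exclude_first) 1L else integer(0),
                 residual_norm = sqrt(best$deviance),
                 message = if (at_bound) "K_D at parameter bound" else ""),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  if (!x$converged) cat("  NOT CONVERGED:", x$message, "\n")
  fmt <- function(v, s) if (is.finite(s)) sprintf("%.4g (SE %.2g)", v, s) else sprintf("%.4g", v)
  cat(sprintf("  K_D = %s uM, dH = %s kcal/mol, n = %s%s\n",
              fmt(x$kd, x$se["kd"]), fmt(x$dh, x$se["dh"]),
              fmt(x$n, x$se["n"]),
              if ("n" %in% x$fixed) " (fixed)" else ""))
  if (isTRUE(x$low_c))
    cat(sprintf("  low-c regime: c = %.2f < 1\n", itc_c_value(x$expt, x$kd, x$n)))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual norm %.4g ucal over %d injections (%d excluded)\n",
              object$residual_norm,
              length(object$expt$heats), length(object$excluded)))
  cat(sprintf("  dG = %.2f kcal/mol at %.1f C\n",
              delta_g_kcal(object$kd, object$expt$temperature),
              object$expt$temperature))
  invisible(object)
}

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = RT \ln(K_D / c^0)} with the 1 M standard state.
#'
#' @param kd dissociation constant (uM).
#' @param temperature_C temperature (degrees C).
#' @return Free energy (kcal/mol), negative for favourable binding.
#' @export
delta_g_kcal <- function(kd, temperature_C = 24) {
  R <- 1.98720425864083e-3            # kcal / (mol K)
  R * (temperature_C + 273.15) * log(kd * 1e-6)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(kd = object$kd, dh = object$dh, n = object$n, baseline = object$baseline)
}

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' @export
predict.itc_fit <- function(object, newdata = NULL, ...) {
  design <- if (is.null(newdata)) object$expt else newdata
  itc_model_heats(design, object$kd, object$dh, object$n, object$baseline)
}

#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = stats::sd(object$residuals), ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            simulate_itc(object$kd, object$dh, object$n, object$expt,
                         q_dilution = object$baseline, noise_sd = noise_sd),
            simplify = FALSE)
}

#' @export
plot.itc_fit <- function(x, ...) {
  conc <- itc_concentrations(x$expt)
  dV <- x$expt$injection_volumes
  ndh <- x$expt$heats / (x$expt$syringe_conc * dV * UCAL_PER_KCALMOL_UM_UL)
  fdh <- x$fitted / (x$expt$syringe_conc * dV * UCAL_PER_KCALMOL_UM_UL)
  plot(conc$molar_ratio, ndh, pch = 16,
       xlab = "molar ratio (ligand/protein)",
       ylab = "kcal per mol of injectant",
       main = "One-site ITC fit", ...)
  lines(conc$molar_ratio, fdh)
  invisible(x)
}

#' Read an ITC experiment from CSV
#'
#' Dialect: `#`-prefixed metadata lines `key = value` for `cell_conc_uM`,
#' `syringe_conc_uM`, `cell_volume_ul`, `temperature_C`, then a CSV header
#' `injection_index,volume_ul,heat_ucal` and one row per injection.
#'
#' @param file path.
#' @return An [itc_experiment()].
#' @export
read_itc <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- lines[startsWith(trimws(lines), "#")]
  meta <- function(key, default = NULL) {
    hit <- grep(key, hdr, value = TRUE)
    if (length(hit) == 0) {
      if (is.null(default)) stop("ITC file missing ", key, call. = FALSE)
      return(default)
    }
    as.numeric(sub(paste0(".*", key, "[ =:]+([0-9.eE+-]+).*"), "\\1", hit[1]))
  }
  body <- utils::read.csv(text = lines[!startsWith(trimws(lines), "#")])
  itc_experiment(cell_conc = meta("cell_conc_uM"),
                 syringe_conc = meta("syringe_conc_uM"),
                 cell_volume = meta("cell_volume_ul", 200),
                 injection_volumes = body$volume_ul,
                 heats = if ("heat_ucal" %in% names(body)) body$heat_ucal else NULL,
                 temperature = meta("temperature_C", 24))
}

#' Write an ITC experiment to CSV
#'
#' @param expt an [itc_experiment()].
#' @param file output path.
#' @export
write_itc <- function(expt, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_conc_uM = %.6g", expt$cell_conc),
               sprintf("# syringe_conc_uM = %.6g", expt$syringe_conc),
               sprintf("# cell_volume_ul = %.6g", expt$cell_volume),
               sprintf("# temperature_C = %.6g", expt$temperature),
               "injection_index,volume_ul,heat_ucal"), con)
  h <- if (is.null(expt$heats)) rep(NA, length(expt$injection_volumes)) else expt$heats
  writeLines(sprintf("%d,%.6g,%.8g", seq_along(expt$injection_volumes),
                     expt$injection_volumes, h), con)
  invisible(file)
}
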