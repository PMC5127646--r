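#' Fraction of protein bound under 1:1 ligand depletion
#'
#' Exact solution of the one-site binding quadratic: with total protein P,
#' total ligand L and dissociation constant K (all uM),
#' \deqn{[PL] = \frac{(P + L + K) - \sqrt{(P + L + K)^2 - 4 P L}}{2}}
#' and the returned value is \eqn{[PL]/P}. Evaluated in the numerically
#' stable form \eqn{2 P L / (b + \sqrt{b^2 - 4 P L})} to avoid cancellation
#' when \eqn{K \ll P, L}.
#'
#' @param protein_tot total protein concentration (uM), > 0.
#' @param ligand_tot total ligand concentration (uM), >= 0; vectorized.
#' @param kd dissociation constant (uM), > 0.
#' @return Fraction bound in `[0, 1]`, same length as the longest input.
#' @export
fraction_bound <- function(protein_tot, ligand_tot, kd) {
  if (any(!is.finite(protein_tot)) || any(!is.finite(ligand_tot)) ||
      any(!is.finite(kd)))
    stop("fraction_bound() inputs must be finite", call. = FALSE)
  if (any(protein_tot <= 0))
    stop("protein_tot must be > 0", call. = FALSE)
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(ligand_tot < 0)) stop("ligand_tot must be >= 0", call. = FALSE)
  b <- protein_tot + ligand_tot + kd
  disc <- pmax(b^2 - 4 * protein_tot * ligand_tot, 0)
  pl <- 2 * protein_tot * ligand_tot / (b + sqrt(disc))
  pmin(pmax(pl / protein_tot, 0), 1)
}

#' Predict fast-exchange titration shifts
#'
#' Under fast exchange the observed combined CSP of each residue is the
#' population-weighted average of free and bound shifts, i.e.
#' \eqn{\Delta\delta(r, i) = \Delta\delta_{max}(r) \cdot f_{bound}(P_i, L_i, K_D)}.
#'
#' @param kd dissociation constant (uM).
#' @param ddmax named numeric vector of per-residue maximal combined shifts
#'   (ppm); names are residue numbers.
#' @param design `data.frame` with columns `protein_conc` and `ligand_conc`
#'   (uM), one row per titration point.
#' @return Matrix of combined CSPs, points x residues.
#' @export
predict_titration <- function(kd, ddmax, design) {
  stopifnot(all(c("protein_conc", "ligand_conc") %in% names(design)))
  f <- fraction_bound(design$protein_conc, design$ligand_conc, kd)
  out <- outer(f, as.numeric(ddmax))
  dimnames(out) <- list(NULL, names(ddmax))
  out
}

#' Apparent dissociation constant for a multivalent ligand
#'
#' First-order statistical-factor model for avidity: a ligand carrying
#' `n_motifs` equivalent binding motifs presents an `n_motifs`-fold higher
#' local site concentration, so \eqn{K_{D,app} = K_D / n}. This is a
#' deliberately simple modeling choice for ranking constructs with tandem
#' motifs; it ignores linker-dependent effective-concentration effects.
#'
#' @param kd_single single-motif dissociation constant (uM).
#' @param n_motifs number of equivalent motifs, >= 1.
#' @return Apparent dissociation constant (uM).
#' @export
apparent_kd_multivalent <- function(kd_single, n_motifs) {
  if (any(n_motifs < 1) || any(n_motifs != round(n_motifs)))
    stop("n_motifs must be an integer >= 1", call. = FALSE)
  kd_single / n_motifs
}

# Extract per-residue CSP trajectories (points x residues) from a series:
# combined CSP of each point against the apo point, residues kept only if
# observed at every point.
series_trajectories <- function(series, weight_H = 10) {
  np <- length(series$points)
  profiles <- lapply(2:np, function(i) csp_profile(series, 1, i, weight_H))
  residues <- Reduce(intersect, lapply(profiles, `[[`, "residue_number"))
  if (length(residues) == 0)
    stop("no residue observed across all titration points", call. = FALSE)
  traj <- rbind(0, t(vapply(profiles, profile_dd, numeric(length(residues)),
                            residues = residues)))
  colnames(traj) <- residues
  design <- data.frame(
    protein_conc = vapply(series$points, `[[`, numeric(1), "protein_conc"),
    ligand_conc = vapply(series$points, `[[`, numeric(1), "ligand_conc"))
  list(trajectories = traj, design = design)
}

# Given KD, the model is linear in ddmax: profile each residue's ddmax out
# analytically and return the residual sum of squares.
titration_profiled_sse <- function(log10_kd, traj, design) {
  f <- fraction_bound(design$protein_conc, design$ligand_conc, 10^log10_kd)
  ff <- sum(f^2)
  if (ff == 0) return(sum(traj^2))
  ddmax <- colSums(traj * f) / ff
  sum((traj - outer(f, ddmax))^2)
}

#' Fit a shared-affinity 1:1 model to NMR titration trajectories
#'
#' Least-squares fit of the fast-exchange model with one global dissociation
#' constant shared across residues and one maximal shift per residue. The
#' profile likelihood in \eqn{\log_{10} K_D} is scanned on a deterministic
#' grid and polished by golden-section search (the per-residue
#' \eqn{\Delta\delta_{max}} enter linearly and are profiled out), then
#' standard errors are taken from a Levenberg-Marquardt pass at the optimum.
#'
#' @param x a [titration_series()], or a numeric matrix of combined-CSP
#'   trajectories (points x residues, first row apo/zero) if `design` is
#'   given.
#' @param design for matrix input: `data.frame` with `protein_conc`,
#'   `ligand_conc` per point.
#' @param kd_range search range for the dissociation constant (uM).
#' @param weight_H proton weighting used when collapsing series shifts.
#' @return An object of class `titration_fit` with components `kd`, `kd_se`,
#'   `ddmax`, `fitted`, `residuals`, `design`, `converged`, `residual_norm`.
#'   Non-identifiable data (all trajectories flat, or a likelihood that
#'   stays flat in K_D) yield `converged = FALSE`.
#' @export
fit_titration <- function(x, design = NULL, kd_range = c(1e-2, 1e6),
                          weight_H = 10) {
  if (inherits(x, "titration_series")) {
    tr <- series_trajectories(x, weight_H)
    traj <- tr$trajectories
    design <- tr$design
  } else {
    traj <- as.matrix(x)
    if (is.null(design))
      stop("matrix input needs a concentration design", call. = FALSE)
  }
  if (nrow(traj) < 3)
    stop("need at least 3 titration points to fit", call. = FALSE)

  fit <- structure(list(kd = NA_real_, kd_se = NA_real_,
                        ddmax = rep(NA_real_, ncol(traj)),
                        design = design, trajectories = traj,
                        converged = FALSE, residual_norm = NA_real_,
                        message = ""),
                   class = "titration_fit")

  if (max(abs(traj)) < 1e-12) {
    fit$message <- "all CSP trajectories are zero; K_D not identifiable"
    return(fit)
  }

  grid <- seq(log10(kd_range[1]), log10(kd_range[2]), length.out = 241)
  sse <- vapply(grid, titration_profiled_sse, numeric(1),
                traj = traj, design = design)
  i <- which.min(sse)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(titration_profiled_sse, c(lo, hi),
                         traj = traj, design = design, tol = 1e-10)
  log_kd <- opt$minimum
  # flat profile likelihood (e.g. no curvature in the ladder) => unreliable
  rel_drop <- (max(sse) - opt$objective) / max(max(sse), .Machine$double.eps)
  at_edge <- i == 1 || i == length(grid)
  kd <- 10^log_kd
  f <- fraction_bound(design$protein_conc, design$ligand_conc, kd)
  ddmax <- colSums(traj * f) / sum(f^2)
  names(ddmax) <- colnames(traj)
  fitted <- outer(f, ddmax)
  dimnames(fitted) <- dimnames(traj)

  fit$kd <- kd
  fit$ddmax <- ddmax
  fit$fitted <- fitted
  fit$residuals <- traj - fitted
  fit$residual_norm <- sqrt(sum(fit$residuals^2))
  fit$converged <- !at_edge && rel_drop > 1e-6
  if (at_edge) fit$message <- "K_D estimate at search-range boundary"

  # SE for KD from an LM pass at the optimum (full parameter vector)
  se <- tryCatch({
    par0 <- c(log_kd, ddmax)
    resid_fun <- function(p) {
      fb <- fraction_bound(design$protein_conc, design$ligand_conc, 10^p[1])
      as.numeric(traj - outer(fb, p[-1]))
    }
    lm_fit <- minpack.lm::nls.lm(par0, fn = resid_fun,
                                 control = minpack.lm::nls.lm.control(maxiter = 200))
    covm <- tryCatch(vcov(lm_fit), error = function(e) NULL)
    if (!is.null(covm)) sqrt(covm[1, 1]) * log(10) * 10^p_or(lm_fit$par[1], log_kd)
    else NA_real_
  }, error = function(e) NA_real_)
  fit$kd_se <- se
  fit
}

p_or <- function(a, b) if (is.finite(a)) a else b

#' @export
print.titration_fit <- function(x, ...) {
  cat("Fast-exchange 1:1 titration fit\n")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$message, "\n")
  }
  cat(sprintf("  K_D = %.4g uM%s\n", x$kd,
              if (is.finite(x$kd_se)) sprintf(" (SE %.2g)", x$kd_se) else ""))
  cat(sprintf("  residues: %d; residual norm %.3g ppm\n",
              length(x$ddmax), x$residual_norm))
  invisible(x)
}

#' @export
summary.titration_fit <- function(object, ...) {
  print(object)
  cat("  per-residue maximal shifts (ppm):\n")
  print(round(object$ddmax, 4))
  invisible(object)
}

#' @export
coef.titration_fit <- function(object, ...) {
  c(kd = object$kd, object$ddmax)
}

#' @export
residuals.titration_fit <- function(object, ...) object$residuals

#' @export
fitted.titration_fit <- function(object, ...) object$fitted

#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_titration(object$kd, object$ddmax, newdata)
}

#' @export
plot.titration_fit <- function(x, ...) {
  ratio <- x$design$ligand_conc / x$design$protein_conc
  matplot(ratio, x$trajectories, pch = 1,
          xlab = "ligand : protein molar ratio",
          ylab = expression(Delta * delta ~ "(ppm)"),
          main = "Fast-exchange titration fit", ...)
  rr <- seq(0, max(ratio), length.out = 100)
  nd <- data.frame(protein_conc = mean(x$design$protein_conc),
                   ligand_conc = rr * mean(x$design$protein_conc))
  matlines(rr, predict(x, nd), lty = 1)
  invisible(x)
}
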