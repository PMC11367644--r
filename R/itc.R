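#' Construct a titration experiment
#'
#' Container for one isothermal titration calorimetry (ITC) run: the cell
#' and syringe concentrations, cell volume, temperature, and the ordered
#' per-injection volumes and integrated heats. Defaults mirror a common
#' protocol for claw-domain/peptide titrations: 0.25 mM macromolecule in
#' the cell, 4 mM peptide in the syringe, 20 degrees C, and a 1 ul priming
#' injection followed by 19 injections of 2 ul.
#'
#' @param injections Data frame with columns `volume_ul` and `heat_ucal`
#'   (integrated heat per injection, microcalories).
#' @param cell_conc Macromolecule concentration in the cell, mM.
#' @param syringe_conc Titrant concentration in the syringe, mM.
#' @param cell_volume Calorimeter cell volume, ul.
#' @param temperature Temperature, Kelvin.
#' @param metadata Free-form provenance list (the synthetic generator
#'   records its ground-truth parameters here).
#' @return An object of class `itc_experiment`.
#' @export
itc_experiment <- function(injections, cell_conc = 0.25, syringe_conc = 4,
                           cell_volume = 200, temperature = 293.15,
                           metadata = list()) {
  injections <- as_tibble(injections)
  stopifnot(all(c("volume_ul", "heat_ucal") %in% names(injections)))
  if (nrow(injections) < 3) abort("an ITC experiment needs >= 3 injections")
  if (any(injections$volume_ul <= 0)) abort("injection volumes must be > 0")
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0) {
    abort("concentrations and cell volume must be > 0")
  }
  if (temperature <= 0) abort("temperature must be > 0 K")
  structure(
    list(injections = injections, cell_conc = cell_conc,
         syringe_conc = syringe_conc, cell_volume = cell_volume,
         temperature = temperature, metadata = metadata),
    class = "itc_experiment"
  )
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "ITC experiment: %d injections, cell %.3g mM / syringe %.3g mM, %.1f ul cell, %.2f K\n",
    nrow(x$injections), x$cell_conc, x$syringe_conc, x$cell_volume,
    x$temperature))
  print(x$injections, n = 5)
  invisible(x)
}

#' @export
as_tibble.itc_experiment <- function(x, ...) x$injections

#' Default claw-domain titration schedule
#'
#' One 1 ul priming injection followed by 19 injections of 2 ul.
#'
#' @return Numeric vector of 20 injection volumes in ul.
#' @export
default_injection_schedule <- function() c(1, rep(2, 19))

# Total titrant and macromolecule concentration (uM) in the cell after each
# injection, under the perfusion picture: each injection of dV displaces an
# equal volume of well-mixed cell content.
cell_concentrations <- function(exp) {
  dV <- exp$injections$volume_ul
  V0 <- exp$cell_volume
  M <- numeric(length(dV))
  X <- numeric(length(dV))
  m <- exp$cell_conc * 1000       # uM
  x <- 0
  Xs <- exp$syringe_conc * 1000   # uM
  for (i in seq_along(dV)) {
    f <- 1 - dV[i] / V0
    m <- m * f
    x <- x * f + Xs * dV[i] / V0
    M[i] <- m
    X[i] <- x
  }
  tibble(Mt = M, Xt = X)
}

# Bound-complex concentration (uM) from the single-site quadratic; takes the
# root lying in [0, min(n*M, X)].
bound_concentration <- function(Mt, Xt, kd, n_sites) {
  b <- Xt + n_sites * Mt + kd
  disc <- b^2 - 4 * n_sites * Mt * Xt
  if (any(disc < 0)) abort("invalid single-site parameters: negative discriminant")
  0.5 * (b - sqrt(disc))
}

#' Forward single-site isotherm: per-injection heats
#'
#' Computes the integrated heat of each injection for a one-site binding
#' model with dissociation constant `kd`, stoichiometry `n_sites` and
#' molar enthalpy `dH`. The cell heat content after injection i is
#' `Q_i = dH * [complex]_i * V0`; the observed per-injection heat applies
#' the standard perfusion (displaced-volume) correction
#' `dQ_i = Q_i - Q_{i-1} + (dV_i/V0) * (Q_i + Q_{i-1}) / 2`.
#'
#' @param kd Dissociation constant, uM; > 0.
#' @param n_sites Stoichiometry (sites per macromolecule); > 0.
#' @param dH Binding enthalpy, kcal/mol.
#' @param exp An [itc_experiment()] (its `heat_ucal` column is ignored).
#' @return Numeric vector of per-injection heats in ucal.
#' @examples
#' e <- itc_experiment(tibble::tibble(
#'   volume_ul = default_injection_schedule(), heat_ucal = 0))
#' isotherm_heats(kd = 10, n_sites = 1, dH = -5, exp = e)
#' @export
isotherm_heats <- function(kd, n_sites, dH, exp) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (kd <= 0 || n_sites <= 0) abort("kd and n_sites must be > 0")
  cc <- cell_concentrations(exp)
  MX <- bound_concentration(cc$Mt, cc$Xt, kd, n_sites)
  V0 <- exp$cell_volume
  # uM * ul -> mol is 1e-12; kcal -> ucal is 1e9; net factor 1e-3
  Q <- dH * MX * V0 * 1e-3
  dV <- exp$injections$volume_ul
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (dV / V0) * (Q + Qprev) / 2
}

#' Wiseman c-value of an experiment
#'
#' `c = n_sites * [cell] / kd`, the parameter governing isotherm curvature
#' and fit identifiability (commonly kept between about 1 and 1000).
#'
#' @inheritParams isotherm_heats
#' @return Dimensionless c-value.
#' @export
c_value <- function(kd, n_sites, exp) n_sites * exp$cell_conc * 1000 / kd

itc_start_grid <- function() {
  starts <- expand.grid(kd = c(0.1, 1, 10, 100, 1000), n = c(0.5, 1, 2),
                        KEEP.OUT.ATTRS = FALSE)
  starts[order(starts$kd, starts$n), , drop = FALSE]
}

#' Fit the single-site binding model to a titration
#'
#' Weighted nonlinear least squares over (kd, n_sites, dH) using the
#' forward model of [isotherm_heats()], with a deterministic multi-start
#' ladder (kd in 0.1/1/10/100/1000 uM crossed with n in 0.5/1/2); the
#' first-converged best-residual start wins. kd and n are optimised on the
#' log scale to keep them positive; standard errors come from the
#' Jacobian at the optimum (delta method for the log-scale parameters).
#'
#' The priming injection is down-weighted to zero by default, standard
#' ITC practice because its effective volume is unreliable.
#'
#' A no-binding decision compares the single-site fit against a
#' constant-offset model with an F test: if the isotherm does not improve
#' on a flat signal at level `no_binding_alpha` (or the signal itself is
#' numerically flat), `no_binding` is set and the thermodynamic fields are
#' NA.
#'
#' @param exp An [itc_experiment()].
#' @param init Optional named list with starting values `kd`, `n`, `dH`;
#'   when given it is tried before the standard grid.
#' @param weights Per-injection weights; default weight 0 on the first
#'   injection, 1 elsewhere.
#' @param no_binding_alpha F-test level for the no-binding rule
#'   (default 0.01).
#' @return An object of class `itc_fit`: fields `kd`, `kd_se`, `n_sites`,
#'   `n_se`, `dH`, `dH_se`, `dG`, `minus_TdS` (kcal/mol), `no_binding`,
#'   `residual_norm` (ucal), `converged`, plus the experiment and fitted
#'   heats. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_single_site <- function(exp, init = NULL, weights = NULL,
                            no_binding_alpha = 0.01) {
  stopifnot(inherits(exp, "itc_experiment"))
  heats <- exp$injections$heat_ucal
  nobs <- length(heats)
  if (is.null(weights)) weights <- c(0, rep(1, nobs - 1))
  stopifnot(length(weights) == nobs, all(weights >= 0))
  w <- sqrt(weights)

  residual_fun <- function(par) {
    model <- isotherm_heats(exp(par[1]), exp(par[2]), par[3], exp)
    w * (heats - model)
  }

  # constant-offset (no-binding) reference model under the same weights
  wsum <- sum(weights)
  offset <- if (wsum > 0) sum(weights * heats) / wsum else 0
  rss0 <- sum(weights * (heats - offset)^2)

  starts <- itc_start_grid()
  dH0 <- {
    # rough enthalpy scale: heat of one injection per moles injected
    mi <- exp$syringe_conc * 1000 * exp$injections$volume_ul[2] /
      exp$cell_volume                        # uM delivered by injection 2
    h2 <- heats[min(2, nobs)]
    d <- h2 / (mi * exp$cell_volume * 1e-3)  # invert the ucal conversion
    if (!is.finite(d) || d == 0) -5 else d
  }
  start_list <- lapply(seq_len(nrow(starts)), function(i) {
    c(log(starts$kd[i]), log(starts$n[i]), dH0)
  })
  if (!is.null(init)) {
    stopifnot(all(c("kd", "n", "dH") %in% names(init)))
    start_list <- c(list(c(log(init$kd), log(init$n), init$dH)), start_list)
  }

  best <- NULL
  for (p0 in start_list) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residual_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-12) best <- fit
  }
  if (is.null(best)) {
    abort("single-site fit failed to converge from any start (multi-start ladder exhausted)")
  }

  par <- best$par
  kd <- exp(par[1]); n_sites <- exp(par[2]); dH <- par[3]
  rss1 <- best$deviance
  dof <- max(wsum_n_effective(weights) - 3, 1)

  # F-test no-binding rule (3 params vs 1)
  flat <- rss0 <= max(1e-12, 1e-16 * max(abs(heats))^2 * nobs)
  p_improve <- if (flat) 1 else {
    Fstat <- ((rss0 - rss1) / 2) / (rss1 / dof)
    if (!is.finite(Fstat) || rss1 <= 0) 0 else pf(Fstat, 2, dof, lower.tail = FALSE)
  }
  no_binding <- flat || p_improve >= no_binding_alpha

  # standard errors via J'J at the optimum, delta method for log-scale pars
  s2 <- rss1 / dof
  se <- rep(NA_real_, 3)
  hess <- try(chol2inv(chol(best$hessian)), silent = TRUE)
  if (!inherits(hess, "try-error")) se <- sqrt(pmax(diag(hess), 0) * s2)
  kd_se <- se[1] * kd
  n_se <- se[2] * n_sites
  dH_se <- se[3]

  fitted <- isotherm_heats(kd, n_sites, dH, exp)
  thermo <- if (no_binding) list(dG = NA_real_, minus_TdS = NA_real_)
            else thermo_decompose(kd, dH, exp$temperature)

  structure(
    list(kd = kd, kd_se = kd_se, n_sites = n_sites, n_se = n_se,
         dH = dH, dH_se = dH_se, dG = thermo$dG, minus_TdS = thermo$minus_TdS,
         no_binding = no_binding, no_binding_p = p_improve,
         residual_norm = sqrt(rss1), converged = TRUE,
         temperature = exp$temperature, fitted = fitted, experiment = exp),
    class = "itc_fit"
  )
}

# effective number of observations with nonzero weight
wsum_n_effective <- function(weights) sum(weights > 0)

#' @export
print.itc_fit <- function(x, ...) {
  if (x$no_binding) {
    cat("Single-site ITC fit: no detectable binding",
        sprintf("(F-test p = %.3g)\n", x$no_binding_p))
    return(invisible(x))
  }
  cat("Single-site ITC fit\n")
  cat(sprintf("  KD = %.4g +/- %.2g uM   N = %.4g +/- %.2g   dH = %.4g +/- %.2g kcal/mol\n",
              x$kd, x$kd_se, x$n_sites, x$n_se, x$dH, x$dH_se))
  cat(sprintf("  dG = %.4g kcal/mol   -TdS = %.4g kcal/mol   (T = %.2f K)\n",
              x$dG, x$minus_TdS, x$temperature))
  invisible(x)
}

#' @rdname fit_single_site
#' @param x,object An `itc_fit` object.
#' @param ... Unused.
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(
    term = c("kd_uM", "n_sites", "dH_kcal_mol"),
    estimate = c(x$kd, x$n_sites, x$dH),
    std.error = c(x$kd_se, x$n_se, x$dH_se)
  )
}

#' @rdname fit_single_site
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(kd_uM = x$kd, n_sites = x$n_sites, dH_kcal_mol = x$dH,
         dG_kcal_mol = x$dG, minus_TdS_kcal_mol = x$minus_TdS,
         no_binding = x$no_binding, residual_norm_ucal = x$residual_norm,
         nobs = nrow(x$experiment$injections))
}

#' Thermodynamic decomposition of a binding constant
#'
#' Standard identities: `dG = R T ln(Kd in molar)` (negative for
#' sub-molar Kd) and `-TdS = dG - dH`, so that `dG = dH + (-TdS)` holds
#' exactly.
#'
#' @param kd Dissociation constant in uM, or an `itc_fit` object (then
#'   `dH` and `temperature` are taken from the fit).
#' @param dH Binding enthalpy, kcal/mol.
#' @param temperature Temperature, Kelvin.
#' @return List with `dG`, `dH`, `minus_TdS` in kcal/mol.
#' @examples
#' thermo_decompose(10, dH = -5, temperature = 293.15)
#' @export
thermo_decompose <- function(kd, dH = NULL, temperature = NULL) {
  if (inherits(kd, "itc_fit")) {
    fit <- kd
    if (fit$no_binding) abort("no binding detected: thermodynamic decomposition undefined")
    dH <- dH %||% fit$dH
    temperature <- temperature %||% fit$temperature
    kd <- fit$kd
  }
  stopifnot(kd > 0, temperature > 0)
  dG <- claw_constants$R_kcal * temperature * log(kd * 1e-6)
  list(dG = dG, dH = dH, minus_TdS = dG - dH)
}
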