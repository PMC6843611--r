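#' Electrolyte conditions
#'
#' Bath conditions for the diffuse-double-layer model. Defaults match a
#' typical planar-bilayer experiment: 20 mM KCl at 295 K in water.
#'
#' @param salt_concentration mol/L of 1:1 electrolyte.
#' @param temperature K.
#' @param relative_permittivity dimensionless (water ~80).
#' @param ion_valence electrolyte valence (must be 1; 1:1 salts only).
#' @return list of class `memion_conditions`.
#' @export
electrolyte_conditions <- function(salt_concentration = 0.020,
                                   temperature = 295,
                                   relative_permittivity = 80,
                                   ion_valence = 1) {
  stopifnot(salt_concentration > 0, temperature > 0,
            relative_permittivity > 0, abs(ion_valence) == 1)
  structure(list(salt_concentration = salt_concentration,
                 temperature = temperature,
                 relative_permittivity = relative_permittivity,
                 ion_valence = 1),
            class = "memion_conditions")
}

#' Adsorption parameters for a charged surfactant
#'
#' @param K Langmuir binding constant, 1/M.
#' @param Gamma_max maximal surface site density, molecules/nm^2.
#' @param valence surfactant charge: +1 (BAC, benzalkonium-like cations) or
#'   -1 (SDS).
#' @return list of class `memion_adsorption_params`.
#' @export
adsorption_params <- function(K, Gamma_max, valence = 1) {
  stopifnot(K > 0, Gamma_max > 0, abs(valence) == 1)
  structure(list(K = K, Gamma_max = Gamma_max, valence = valence),
            class = "memion_adsorption_params")
}

# Grahame prefactor sqrt(8 eps0 eps_r R T c) in C/m^2, c in mol/L
.grahame_A <- function(cond) {
  sqrt(8 * .const$eps0 * cond$relative_permittivity * .const$R *
         cond$temperature * cond$salt_concentration * 1000)
}

#' Grahame equation: surface potential from surface charge density
#'
#' For a 1:1 electrolyte the diffuse-layer (Gouy-Chapman) theory gives
#' `psi0 = (2RT/F) asinh( sigma / sqrt(8 eps0 eps_r R T c) )`.
#' `grahame_sigma()` is the exact inverse.
#'
#' @param sigma surface charge density, e/nm^2 (may be a vector).
#' @param cond an [electrolyte_conditions()] object.
#' @return Surface potential psi0 in mV.
#' @export
grahame_psi <- function(sigma, cond = electrolyte_conditions()) {
  if (any(!is.finite(sigma))) stop("surface charge density must be finite")
  sigma_si <- sigma * .const$e * 1e18          # e/nm^2 -> C/m^2
  RT <- .const$R * cond$temperature
  1000 * (2 * RT / .const$F) * asinh(sigma_si / .grahame_A(cond))
}

#' @rdname grahame_psi
#' @param psi_mV surface potential, mV.
#' @return `grahame_sigma`: surface charge density in e/nm^2.
#' @export
grahame_sigma <- function(psi_mV, cond = electrolyte_conditions()) {
  if (any(!is.finite(psi_mV))) stop("surface potential must be finite")
  RT <- .const$R * cond$temperature
  sigma_si <- .grahame_A(cond) * sinh((psi_mV / 1000) * .const$F / (2 * RT))
  sigma_si / (.const$e * 1e18)
}

#' Inverse Debye length (1/nm)
#'
#' @param cond an [electrolyte_conditions()] object.
#' @return kappa in 1/nm.
#' @export
debye_kappa <- function(cond = electrolyte_conditions()) {
  RT <- .const$R * cond$temperature
  k_m <- sqrt(2 * .const$F^2 * cond$salt_concentration * 1000 /
                (.const$eps0 * cond$relative_permittivity * RT))
  k_m * 1e-9
}

#' Boundary-potential curve container
#'
#' @param conc_uM bulk concentrations, micromolar, strictly increasing.
#' @param dphi_mV boundary-potential differences, mV.
#' @param method `"IFC"`, `"NONACTIN"` or `"MODEL"`.
#' @return data.frame of class `memion_bp_curve` with attribute `method`.
#' @export
boundary_potential_curve <- function(conc_uM, dphi_mV,
                                     method = c("MODEL", "IFC", "NONACTIN")) {
  method <- match.arg(method)
  stopifnot(length(conc_uM) == length(dphi_mV))
  if (any(diff(conc_uM) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(!is.finite(dphi_mV))) stop("potentials must be finite")
  structure(data.frame(conc_uM = conc_uM, dphi_mV = dphi_mV),
            class = c("memion_bp_curve", "data.frame"), method = method)
}

#' Self-consistent adsorption model for the boundary-potential curve
#'
#' For each bulk concentration, solves the coupled Langmuir/Gouy-Chapman
#' system: surface concentration `c_s = c exp(-z F psi0 / RT)` (Boltzmann
#' enhancement or depletion of the charged surfactant at the charged
#' surface), coverage `Gamma = Gamma_max K c_s / (1 + K c_s)`, surface charge
#' `sigma = z Gamma`, and `psi0 = grahame_psi(sigma)`, iterated (damped fixed
#' point) to |delta psi0| < `tol` mV. The boundary-potential change is
#' identified with psi0: the model attributes measured changes entirely to
#' the diffuse layer, consistent with IFC and carrier-conductance potentials
#' coinciding when adsorbed ions do not perturb the dipole layer.
#'
#' @param params an [adsorption_params()] object.
#' @param cond an [electrolyte_conditions()] object.
#' @param conc_uM bulk concentrations, micromolar.
#' @param feedback if FALSE, skip the Boltzmann surface-concentration factor
#'   (naive Langmuir followed by Grahame, no self-consistency).
#' @param tol convergence tolerance on psi0, mV.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   last residual.
#' @return A `memion_bp_curve` with method `"MODEL"`.
#' @export
adsorption_curve <- function(params, cond = electrolyte_conditions(),
                             conc_uM, feedback = TRUE,
                             tol = 1e-6, max_iter = 1e4) {
  stopifnot(inherits(params, "memion_adsorption_params"),
            all(conc_uM > 0))
  RT <- .const$R * cond$temperature
  z <- params$valence
  dphi <- vapply(conc_uM, function(cu) {
    c_M <- cu * 1e-6
    psi <- 0
    if (!feedback) {
      Gamma <- params$Gamma_max * params$K * c_M / (1 + params$K * c_M)
      return(grahame_psi(z * Gamma, cond))
    }
    lambda <- 0.5
    for (it in seq_len(max_iter)) {
      cs <- c_M * exp(-z * .const$F * (psi / 1000) / RT)
      Gamma <- params$Gamma_max * params$K * cs / (1 + params$K * cs)
      psi_new <- grahame_psi(z * Gamma, cond)
      delta <- psi_new - psi
      if (abs(delta) < tol) return(psi_new)
      psi <- psi + lambda * delta
    }
    stop("adsorption self-consistency did not converge after ", max_iter,
         " iterations (last residual ", signif(abs(delta), 3), " mV)")
  }, numeric(1))
  boundary_potential_curve(conc_uM, dphi, method = "MODEL")
}

#' Fit the adsorption model to a boundary-potential curve
#'
#' Least-squares fit of `(K, Gamma_max)` so that [adsorption_curve()]
#' reproduces the measured potentials, by Levenberg-Marquardt on the log
#' parameters (both are positive scale parameters).
#'
#' @param curve a `memion_bp_curve` (>= 4 points).
#' @param cond an [electrolyte_conditions()] object.
#' @param valence surfactant valence, +1 or -1.
#' @param start optional named start values `c(K=, Gamma_max=)`.
#' @param feedback passed to [adsorption_curve()].
#' @return Object of class `memion_adsorption_fit` with `coefficients`
#'   (K, Gamma_max), `residuals`, `rss`, `converged`, `identifiable`.
#' @export
fit_adsorption <- function(curve, cond = electrolyte_conditions(),
                           valence = 1, start = NULL, feedback = TRUE) {
  stopifnot(inherits(curve, "data.frame"), nrow(curve) >= 4L)
  y <- curve$dphi_mV
  cu <- curve$conc_uM
  identifiable <- stats::sd(y) > 1e-9 && max(abs(y)) > 1e-6
  if (!identifiable) {
    warning("flat/degenerate curve: adsorption parameters are unidentifiable")
    return(structure(list(coefficients = c(K = NA_real_, Gamma_max = NA_real_),
                          residuals = y * NA, rss = NA_real_,
                          fitted = y * NA, curve = curve, cond = cond,
                          valence = valence, converged = FALSE,
                          identifiable = FALSE, feedback = feedback),
                     class = "memion_adsorption_fit"))
  }
  if (is.null(start)) {
    # half-saturation concentration and saturation potential heuristics
    ymax <- max(abs(y))
    c_half <- cu[which.min(abs(abs(y) - ymax / 2))] * 1e-6
    G0 <- max(abs(grahame_sigma(max(abs(y)) * sign(valence) * 1.05, cond)), 1e-4)
    start <- c(K = 1 / max(c_half, 1e-12), Gamma_max = G0)
  }
  resid_fun <- function(p) {
    pr <- adsorption_params(exp(p[1]), exp(p[2]), valence)
    tryCatch(adsorption_curve(pr, cond, cu, feedback = feedback)$dphi_mV - y,
             error = function(e) rep(1e6, length(y)))
  }
  fit <- minpack.lm::nls.lm(par = log(unname(start)), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  coefs <- exp(fit$par)
  names(coefs) <- c("K", "Gamma_max")
  res <- resid_fun(fit$par)
  structure(list(coefficients = coefs, residuals = res,
                 rss = sum(res^2), fitted = y + res,
                 curve = curve, cond = cond, valence = valence,
                 converged = fit$info %in% 1:4, identifiable = TRUE,
                 feedback = feedback, nls_info = fit$info),
            class = "memion_adsorption_fit")
}

#' @export
print.memion_adsorption_fit <- function(x, ...) {
  cat("Gouy-Chapman/Langmuir adsorption fit (valence ",
      sprintf("%+d", x$valence), ")\n", sep = "")
  if (!x$identifiable) {
    cat("  parameters unidentifiable (flat curve)\n")
    return(invisible(x))
  }
  cat(sprintf("  K         = %.4g 1/M\n", x$coefficients["K"]))
  cat(sprintf("  Gamma_max = %.4g molecules/nm^2\n", x$coefficients["Gamma_max"]))
  cat(sprintf("  RSS = %.4g mV^2 over %d points; converged: %s\n",
              x$rss, nrow(x$curve), x$converged))
  invisible(x)
}

#' @export
coef.memion_adsorption_fit <- function(object, ...) object$coefficients

#' @export
residuals.memion_adsorption_fit <- function(object, ...) object$residuals

#' @export
summary.memion_adsorption_fit <- function(object, ...) {
  print(object)
  if (object$identifiable)
    cat(sprintf("  residual SD = %.3g mV\n",
                sqrt(object$rss / max(1, nrow(object$curve) - 2))))
  invisible(object)
}

#' @export
predict.memion_adsorption_fit <- function(object, conc_uM = NULL, ...) {
  if (!object$identifiable) stop("cannot predict from an unidentifiable fit")
  if (is.null(conc_uM)) conc_uM <- object$curve$conc_uM
  pr <- adsorption_params(object$coefficients["K"],
                          object$coefficients["Gamma_max"], object$valence)
  adsorption_curve(pr, object$cond, conc_uM, feedback = object$feedback)$dphi_mV
}

#' @export
plot.memion_adsorption_fit <- function(x, ...) {
  graphics::plot(x$curve$conc_uM, x$curve$dphi_mV, log = "x",
                 xlab = "concentration (uM)", ylab = "delta Phi_b (mV)", ...)
  if (x$identifiable) {
    cg <- exp(seq(log(min(x$curve$conc_uM)), log(max(x$curve$conc_uM)),
                  length.out = 50))
    graphics::lines(cg, predict(x, cg))
  }
  invisible(x)
}

#' IFC capacitance scan container
#'
#' @param applied_voltage_mV applied transmembrane voltages, mV.
#' @param capacitance membrane capacitance, arbitrary units, all > 0.
#' @return data.frame of class `memion_ifc_scan`.
#' @export
ifc_scan <- function(applied_voltage_mV, capacitance) {
  stopifnot(length(applied_voltage_mV) == length(capacitance))
  if (any(capacitance <= 0)) stop("capacitance must be positive")
  structure(data.frame(applied_voltage_mV = applied_voltage_mV,
                       capacitance = capacitance),
            class = c("memion_ifc_scan", "data.frame"))
}

#' Estimate the intramembrane potential from an IFC capacitance scan
#'
#' Electrostriction makes the membrane capacitance a parabola in the applied
#' voltage, `C(U) = C0 (1 + alpha (U - Phi_in)^2)`: the capacitance is
#' minimal (the membrane thickest) when the applied voltage exactly
#' compensates the inner field, so the vertex locates Phi_in. The parabola is
#' fitted exactly via its quadratic expansion with `lm`; the vertex standard
#' error comes from the delta method.
#'
#' @param scan a `memion_ifc_scan` or data.frame with columns
#'   `applied_voltage_mV`, `capacitance` (>= 5 points bracketing the minimum).
#' @return Object of class `memion_ifc_fit`: `phi_in` (mV), `se`, `C0`,
#'   `alpha` (1/mV^2), `fitted`.
#' @export
estimate_phi_in <- function(scan) {
  U <- scan$applied_voltage_mV
  C <- scan$capacitance
  if (length(U) < 5L) stop("need at least 5 scan points")
  fit <- stats::lm(C ~ U + I(U^2))
  a <- stats::coef(fit)
  if (!is.finite(a[3]) || a[3] <= 0)
    stop("no capacitance minimum in the scanned range (non-convex scan)")
  phi <- -a[2] / (2 * a[3])
  if (phi < min(U) || phi > max(U))
    stop("capacitance minimum (", signif(phi, 4),
         " mV) lies outside the scanned range [", min(U), ", ", max(U), "] mV")
  # a noise-free scan fits exactly; vcov then warns about a perfect fit
  V <- suppressWarnings(stats::vcov(fit)[2:3, 2:3])
  g <- c(-1 / (2 * a[3]), a[2] / (2 * a[3]^2))
  se <- sqrt(drop(t(g) %*% V %*% g))
  C0 <- unname(a[1] - a[2]^2 / (4 * a[3]))
  alpha <- unname(a[3] / C0)
  structure(list(phi_in = unname(phi), se = se, C0 = C0, alpha = alpha,
                 fitted = stats::fitted(fit), scan = scan, lm = fit),
            class = "memion_ifc_fit")
}

#' @export
print.memion_ifc_fit <- function(x, ...) {
  cat(sprintf("IFC fit: Phi_in = %.3f +/- %.3f mV (C0 = %.4g, alpha = %.3g 1/mV^2)\n",
              x$phi_in, x$se, x$C0, x$alpha))
  invisible(x)
}

#' @export
plot.memion_ifc_fit <- function(x, ...) {
  graphics::plot(x$scan$applied_voltage_mV, x$scan$capacitance,
                 xlab = "applied voltage (mV)", ylab = "capacitance (a.u.)", ...)
  o <- order(x$scan$applied_voltage_mV)
  graphics::lines(x$scan$applied_voltage_mV[o], x$fitted[o])
  graphics::abline(v = x$phi_in, lty = 3)
  invisible(x)
}

#' Boundary-potential change from nonactin conductance
#'
#' Nonactin carries monovalent cations; an added boundary potential changes
#' the electrostatic barrier and the membrane conductance by a Boltzmann
#' factor, so `delta Phi_b = (RT/F) ln(G0 / G)`. Positive adsorbed charge
#' raises the barrier for the cation complex and lowers G, giving a positive
#' potential change.
#'
#' @param G conductance in the presence of the tested substance (vectorised).
#' @param G0 reference conductance before addition.
#' @param temperature K.
#' @return delta Phi_b in mV.
#' @export
nonactin_delta_phi <- function(G, G0, temperature = 295) {
  if (any(G <= 0) || any(G0 <= 0)) stop("conductances must be positive")
  1000 * (.const$R * temperature / .const$F) * log(G0 / G)
}
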