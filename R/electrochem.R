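#' Physical constants for membrane electrochemistry
#'
#' Bundles the Faraday constant, the gas constant, the working temperature and
#' the temperature-dependent ion product of water. All concentrations in this
#' package are held in mol/cm^3, so `Kw` is returned in (mol/cm^3)^2.
#'
#' @param temperature Absolute temperature in K. Default 294.15 K (21 degC),
#'   the temperature at which GUV permeation assays are typically run.
#' @return A list with components `F_const` (C/mol), `R_const` (J/mol/K),
#'   `temperature` (K) and `Kw` ((mol/cm^3)^2).
#' @examples
#' phys_constants()$Kw
#' @export
phys_constants <- function(temperature = 294.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  # Harned & Owen empirical fit for pKw(T) in molar units; /1e6 -> (mol/cm^3)^2
  pKw <- 4470.99 / temperature - 6.0875 + 0.01706 * temperature
  list(
    F_const = 96485,
    R_const = 8.314,
    temperature = temperature,
    Kw = 10^(-pKw) / 1e6
  )
}

#' Goldman-Hodgkin-Katz flux density for a monovalent cation
#'
#' Electrodiffusive flux of a monovalent cation (here H+) across a membrane
#' under combined concentration and electrical gradients,
#' \deqn{J = P u \frac{[C]_o - [C]_i e^{u}}{e^{u} - 1}, \quad u = \frac{\Delta\psi F}{RT},}
#' with the inward-positive convention and \eqn{\Delta\psi = \psi_{in} - \psi_{out}}.
#' At \eqn{\Delta\psi = 0} this reduces to Fick's law
#' \eqn{J = P([C]_o - [C]_i)}. For \eqn{|u| < 10^{-6}} the second-order series
#' \eqn{J = P([C]_o - [C]_i) - P u ([C]_o + [C]_i)/2} is used so the function
#' is smooth and finite through \eqn{u = 0}.
#'
#' For a monovalent anion, call with the potential negated and the
#' concentration roles swapped accordingly (see [simulate_acidification()]).
#'
#' @param P Permeability coefficient, cm/s (>= 0).
#' @param dpsi Transmembrane potential psi_in - psi_out, V. Vectorised.
#' @param H_i,H_o Internal / external concentration, mol/cm^3. Vectorised.
#' @param temperature Temperature in K.
#' @return Flux density in mol/cm^2/s, positive inward.
#' @examples
#' ghk_flux(1.9e-3, 0, 10^-7.6 / 1000, 10^-6.9 / 1000)
#' @export
ghk_flux <- function(P, dpsi, H_i, H_o, temperature = 294.15) {
  if (!all(is.finite(P), is.finite(dpsi), is.finite(H_i), is.finite(H_o),
           is.finite(temperature))) {
    stop("ghk_flux: all inputs must be finite")
  }
  if (any(P < 0)) stop("ghk_flux: P must be >= 0")
  cst <- phys_constants(temperature)
  u <- dpsi * cst$F_const / (cst$R_const * cst$temperature)
  n <- max(length(u), length(H_i), length(H_o), length(P))
  u <- rep_len(u, n); H_i <- rep_len(H_i, n); H_o <- rep_len(H_o, n)
  P <- rep_len(P, n)
  J <- numeric(n)
  small <- abs(u) < 1e-6
  J[small] <- P[small] * (H_o[small] - H_i[small]) -
    P[small] * u[small] * (H_o[small] + H_i[small]) / 2
  if (any(!small)) {
    ub <- u[!small]
    J[!small] <- P[!small] * ub * (H_o[!small] - H_i[!small] * exp(ub)) / expm1(ub)
  }
  J
}

#' Invert the GHK flux equation for the transmembrane potential
#'
#' Solves `ghk_flux(P, dpsi, H_i, H_o) = J` for `dpsi` by bracketed root
#' finding. The GHK flux is strictly decreasing in `dpsi` for a cation at
#' fixed concentrations, so the root is unique. This is the analysis-direction
#' operation: a measured flux profile plus the linear-regime permeability
#' yields the potential buildup with `dpsi` as the only free parameter.
#'
#' @param J Measured flux density, mol/cm^2/s (inward positive). Vectorised.
#' @param P Permeability coefficient, cm/s (> 0).
#' @param H_i,H_o Internal / external concentration, mol/cm^3.
#' @param temperature Temperature in K.
#' @param bracket Search interval for dpsi in V, default +/- 0.3 V.
#' @return dpsi in V (psi_in - psi_out).
#' @examples
#' J <- ghk_flux(1.9e-3, 0.045, 10^-7.6 / 1000, 10^-6.9 / 1000)
#' invert_ghk(J, 1.9e-3, 10^-7.6 / 1000, 10^-6.9 / 1000)
#' @export
invert_ghk <- function(J, P, H_i, H_o, temperature = 294.15,
                       bracket = c(-0.3, 0.3)) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  if (any(P <= 0)) stop("invert_ghk: P must be > 0")
  n <- max(length(J), length(H_i), length(H_o))
  J <- rep_len(J, n); H_i <- rep_len(H_i, n); H_o <- rep_len(H_o, n)
  vapply(seq_len(n), function(k) {
    J_hi <- ghk_flux(P, bracket[1], H_i[k], H_o[k], temperature)
    J_lo <- ghk_flux(P, bracket[2], H_i[k], H_o[k], temperature)
    if (J[k] > J_hi) {
      stop(sprintf(
        "invert_ghk: J = %.3g exceeds the maximum attainable flux %.3g at dpsi = %.3f V",
        J[k], J_hi, bracket[1]))
    }
    if (J[k] < J_lo) {
      stop(sprintf(
        "invert_ghk: J = %.3g is below the minimum attainable flux %.3g at dpsi = %.3f V",
        J[k], J_lo, bracket[2]))
    }
    stats::uniroot(
      function(v) ghk_flux(P, v, H_i[k], H_o[k], temperature) - J[k],
      interval = bracket, tol = 1e-9
    )$root
  }, numeric(1))
}

#' Proton motive force
#'
#' \deqn{pmf = \Delta\psi - \ln(10)\frac{RT}{F}(pH_i - pH_o)}
#' the total electrochemical driving force on protons across the membrane.
#'
#' @param dpsi Transmembrane potential psi_in - psi_out, V. Vectorised.
#' @param pH_i,pH_o Lumenal and external pH.
#' @param temperature Temperature in K.
#' @return pmf in V.
#' @examples
#' pmf(0.045, 7.43, 6.9) * 1000  # in mV
#' @export
pmf <- function(dpsi, pH_i, pH_o, temperature = 294.15) {
  if (!all(is.finite(dpsi), is.finite(pH_i), is.finite(pH_o))) {
    stop("pmf: all inputs must be finite")
  }
  cst <- phys_constants(temperature)
  dpsi - log(10) * cst$R_const * cst$temperature / cst$F_const * (pH_i - pH_o)
}

#' Build a potential / pmf trace table
#'
#' @param times Time points, s.
#' @param dpsi Transmembrane potential series, V.
#' @param pH_i,pH_o pH series.
#' @param temperature Temperature in K.
#' @return data.frame with columns `times`, `dpsi`, `pmf`, `dpH`
#'   (`pH_i - pH_o`), all potentials in V.
#' @export
potential_trace <- function(times, dpsi, pH_i, pH_o, temperature = 294.15) {
  stopifnot(length(times) == length(dpsi), length(dpsi) == length(pH_i),
            length(pH_i) == length(pH_o))
  data.frame(
    times = times, dpsi = dpsi,
    pmf = pmf(dpsi, pH_i, pH_o, temperature),
    dpH = pH_i - pH_o
  )
}

#' Diffusion time across an unstirred layer
#'
#' Characteristic time `r^2 / (6 D)` for a solute to diffuse from the membrane
#' to the centre of a spherical vesicle of radius `r`. For a 10 um GUV and the
#' proton diffusion coefficient 9.3e-5 cm^2/s this is about 2 ms, far below
#' typical frame intervals, so the lumen may be treated as well mixed.
#'
#' @param r Radius, cm.
#' @param D Diffusion coefficient, cm^2/s.
#' @return Time in s.
#' @examples
#' unstirred_layer_time(1e-3, 9.3e-5)
#' @export
unstirred_layer_time <- function(r, D) {
  stopifnot(all(r > 0), all(D > 0))
  r^2 / (6 * D)
}

#' Decompose a weak-acid permeability into ionic and neutral pathways
#'
#' Given the total effective permeability measured after weak-acid addition
#' (protons arriving both as free H+ and as the neutral acid HA) and the pure
#' H+ permeability measured with a strong acid under identical conditions, the
#' neutral-acid component is the difference `P_HA = P_total - P_Hplus`; the
#' fraction of protons crossing as H+ is `P_Hplus / P_total`.
#'
#' @param P_total Total effective permeability (weak acid), cm/s.
#' @param P_Hplus Proton-only permeability (strong acid), cm/s.
#' @return An object of class `decomposition_result`: list with `P_total`,
#'   `P_Hplus`, `P_HA`, `ratio` (= P_HA / P_Hplus) and `fraction_ionic`
#'   (= P_Hplus / P_total).
#' @examples
#' decompose_weak_acid(3.1e-2, 6.2e-3)
#' @export
decompose_weak_acid <- function(P_total, P_Hplus) {
  stopifnot(is.numeric(P_total), is.numeric(P_Hplus),
            length(P_total) == 1L, length(P_Hplus) == 1L)
  if (!(P_Hplus > 0)) stop("decompose_weak_acid: P_Hplus must be > 0")
  if (P_Hplus > P_total) {
    stop("decompose_weak_acid: P_Hplus exceeds P_total; ",
         "a negative neutral-acid flux is unphysical")
  }
  out <- list(
    P_total = P_total,
    P_Hplus = P_Hplus,
    P_HA = P_total - P_Hplus,
    ratio = (P_total - P_Hplus) / P_Hplus,
    fraction_ionic = P_Hplus / P_total
  )
  class(out) <- "decomposition_result"
  out
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(
    "Weak-acid flux decomposition\n  P_total  = %.3g cm/s\n  P_H+     = %.3g cm/s\n  P_HA     = %.3g cm/s\n  P_HA/P_H+ = %.3g\n  ionic fraction = %.3g\n",
    x$P_total, x$P_Hplus, x$P_HA, x$ratio, x$fraction_ionic))
  invisible(x)
}

#' Anion-to-neutral-acid concentration ratio of a weak acid
#'
#' Henderson-Hasselbalch ratio `[A-]/[HA] = 10^(pH - pKa)`. For formic acid
#' (pKa 3.75) at pH 7.6 this is ~1e4: the undissociated form is a trace
#' species, so its transmembrane gradient tracks the proton gradient.
#'
#' @param pH pH. Vectorised.
#' @param pKa Acid dissociation constant, pH units.
#' @return Dimensionless ratio.
#' @examples
#' dissociation_ratio(7.6, 3.75)
#' @export
dissociation_ratio <- function(pH, pKa) {
  if (!all(is.finite(pH), is.finite(pKa))) {
    stop("dissociation_ratio: inputs must be finite")
  }
  10^(pH - pKa)
}
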