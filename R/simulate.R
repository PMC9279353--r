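#' Acid species
#'
#' Describes the added acid. Strong acids (HCl, HNO3) are fully dissociated:
#' use `pKa = -Inf` (the "fully dissociated" sentinel), under which the
#' neutral-form concentration is identically zero and `P_HA` is ignored.
#'
#' @param name Acid name.
#' @param pKa Acid dissociation constant, pH units; `-Inf` for strong acids.
#' @param P_HA Permeability of the neutral (protonated) form, cm/s.
#' @param P_anion Permeability of the conjugate anion, cm/s. Default 1e-10,
#'   the order of measured halide permeabilities across PC bilayers.
#' @return An object of class `acid_species`.
#' @examples
#' strong_acid("HCl")
#' formic_acid()
#' @export
acid_species <- function(name, pKa, P_HA = 0, P_anion = 1e-10) {
  stopifnot(P_HA >= 0, P_anion >= 0)
  structure(list(name = name, pKa = pKa, P_HA = P_HA, P_anion = P_anion),
            class = "acid_species")
}

#' @rdname acid_species
#' @export
strong_acid <- function(name = "HCl", P_anion = 1e-10) {
  acid_species(name, pKa = -Inf, P_HA = 0, P_anion = P_anion)
}

#' @rdname acid_species
#' @param P_HA Neutral-form permeability for the weak-acid preset, cm/s.
#'   Default 1.3e-3, sized so that the effective flux-vs-gradient slope of
#'   formic acid is a few-fold that of H+ under default assay conditions
#'   (see [calibrate_neutral_permeability()]).
#' @export
formic_acid <- function(P_HA = 1.3e-3, P_anion = 1e-10) {
  acid_species("HCOOH", pKa = 3.75, P_HA = P_HA, P_anion = P_anion)
}

#' External pH course after acid addition
#'
#' A pipetted bolus of acid diffuses to the resting vesicles, so the
#' extravesicular pH holds at `pH_initial` until `arrival_time` and then
#' relaxes exponentially (time constant `tau`) to `pH_final`.
#'
#' @param pH_initial Resting external pH. Default 7.6.
#' @param pH_final Acidified plateau pH; must be below `pH_initial` and is
#'   kept above the pyranine quench point in the defaults. Default 6.9.
#' @param arrival_time Time of proton arrival at the vesicle, s. Default 60.
#' @param tau Exponential approach time constant, s (> 0). Default 120.
#' @return An object of class `external_course`.
#' @export
external_course <- function(pH_initial = 7.6, pH_final = 6.9,
                            arrival_time = 60, tau = 120) {
  stopifnot(pH_final < pH_initial, tau > 0, arrival_time >= 0)
  structure(list(pH_initial = pH_initial, pH_final = pH_final,
                 arrival_time = arrival_time, tau = tau),
            class = "external_course")
}

#' Evaluate the external pH course
#'
#' @param t Time, s (>= 0). Vectorised.
#' @param course An [external_course()].
#' @return External pH at `t`; continuous at the arrival time.
#' @examples
#' external_ph(c(0, 180), external_course())
#' @export
external_ph <- function(t, course) {
  stopifnot(all(t >= 0), inherits(course, "external_course"))
  ifelse(
    t < course$arrival_time,
    course$pH_initial,
    course$pH_final + (course$pH_initial - course$pH_final) *
      exp(-(t - course$arrival_time) / course$tau)
  )
}

#' Forward-simulation configuration for one vesicle
#'
#' @param radius Vesicle radius, cm (> 0). Default 1e-3 (10 um).
#' @param P_Hplus Proton permeability coefficient, cm/s. Default 1.9e-3, the
#'   mean measured for charged PC:PG GUVs.
#' @param acid An [acid_species()]. Default [strong_acid()].
#' @param buffer A [buffer_system()]. Default [hepes_buffer()].
#' @param external An [external_course()].
#' @param C_spec Effective specific membrane capacitance, F/cm^2. Default
#'   5e-4, sized so that the potential builds over the experiment timescale
#'   rather than within a single frame (see the methods vignette).
#' @param dt Integration step, s (> 0). Default 0.05.
#' @param duration Simulated time, s. Default 600.
#' @param record_interval Output sampling interval, s; should match the
#'   imaging frame interval. Default 5.
#' @param clamp_potential If TRUE the potential is clamped at 0 V and the
#'   flux follows Fick's law throughout. Default FALSE.
#' @param vesicle_id Integer ID carried into the output trace.
#' @param seed Integer seed recorded with the configuration (the forward
#'   model itself is deterministic; the seed feeds any downstream rendering).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(radius = 1e-3, P_Hplus = 1.9e-3,
                              acid = strong_acid(), buffer = hepes_buffer(),
                              external = external_course(),
                              C_spec = 5e-4, dt = 0.05, duration = 600,
                              record_interval = 5, clamp_potential = FALSE,
                              vesicle_id = 1L, seed = 1L) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("simulation_config: an explicit integer seed is required")
  }
  stopifnot(radius > 0, P_Hplus >= 0, C_spec > 0, dt > 0,
            inherits(acid, "acid_species"), inherits(buffer, "buffer_system"),
            inherits(external, "external_course"),
            record_interval >= dt)
  if (duration < dt) stop("simulation_config: duration must be >= dt")
  structure(
    list(radius = radius, P_Hplus = P_Hplus, acid = acid, buffer = buffer,
         external = external, C_spec = C_spec, dt = dt, duration = duration,
         record_interval = record_interval,
         clamp_potential = clamp_potential,
         vesicle_id = as.integer(vesicle_id), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Neutral-form concentration of the weak acid on one membrane face:
# Henderson-Hasselbalch speciation of the total acid pool at that face's pH.
neutral_fraction <- function(pH, pKa) {
  r <- 10^(pKa - pH)
  r / (1 + r)
}

#' Simulate single-GUV acidification
#'
#' Integrates the forward model of the acid-addition assay with a fixed-step
#' explicit scheme (classical RK4 via deSolve):
#' \itemize{
#'   \item proton influx by GHK electrodiffusion, [ghk_flux()];
#'   \item conjugate-anion influx by the same GHK form with valence -1;
#'   \item neutral weak-acid influx `J_HA = P_HA ([HA]_o - [HA]_i)` with
#'     instantaneous Henderson-Hasselbalch speciation on each face;
#'   \item lumenal buffering `dpH_i/dt = -(d[H+]T_in/dt) / beta(pH_i)` with
#'     `d[H+]T_in/dt = (J_H+ + J_HA) * (3/r)`;
#'   \item capacitive potential buildup
#'     `d(dpsi)/dt = F (J_H+ - J_anion) / C_spec` (identically zero when
#'     `clamp_potential = TRUE`).
#' }
#' The external acid pool follows the configured [external_course()]; the
#' amount of added acid (hence the external anion and total-acid
#' concentrations) is recovered from the course by the closed-form buffer
#' titration function [titration_acid_added()].
#'
#' @param config A [simulation_config()].
#' @return An object of class `guv_trace`: data.frame with columns
#'   `vesicle_id`, `times` (s), `pH_o`, `pH_i`, `dpsi` (V), `J_Hplus`,
#'   `J_HA`, `J_anion` (mol/cm^2/s), `cum_protons` (mol/cm^3) plus
#'   attributes `radius` (cm) and `config`.
#' @examples
#' tr <- simulate_acidification(simulation_config(duration = 50))
#' head(tr)
#' @export
simulate_acidification <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  acid <- config$acid
  buffer <- config$buffer
  Temp <- buffer$temperature
  A_over_V <- 3 / config$radius
  cst <- phys_constants(Temp)
  strong <- !is.finite(acid$pKa)

  # hoisted constants for the derivative (hot path of the RK4 loop)
  F_RT <- cst$F_const / (cst$R_const * Temp)
  Kw <- cst$Kw
  ln10 <- log(10)
  Ka_buf <- 10^(-buffer$components$pKa) / 1000
  C_buf <- buffer$components$conc
  pH0 <- config$external$pH_initial
  pHf <- config$external$pH_final
  t_arr <- config$external$arrival_time
  tau <- config$external$tau
  P_H <- config$P_Hplus
  P_An <- acid$P_anion
  P_HA <- acid$P_HA
  pKa_acid <- acid$pKa
  clamp <- config$clamp_potential
  Fc <- cst$F_const
  C_spec <- config$C_spec

  net_base <- function(p) {
    H <- 10^(-p) / 1000
    Kw / H - H + sum(C_buf * Ka_buf / (Ka_buf + H))
  }
  nb_ref <- net_base(pH0)

  ghk1 <- function(P, u, Ci, Co) {
    # inward-positive GHK, scalar, series limit through u = 0
    if (abs(u) < 1e-6) {
      P * (Co - Ci) - P * u * (Co + Ci) / 2
    } else {
      P * u * (Co - Ci * exp(u)) / expm1(u)
    }
  }

  deriv <- function(t, y, parms) {
    y <- unname(y)
    pH_i <- y[1]
    pH_o <- if (t < t_arr) pH0 else pHf + (pH0 - pHf) * exp(-(t - t_arr) / tau)
    H_i <- 10^(-pH_i) / 1000
    H_o <- 10^(-pH_o) / 1000
    dpsi <- if (clamp) 0 else y[3]
    u <- dpsi * F_RT
    added <- max(nb_ref - net_base(pH_o), 0)

    J_H <- ghk1(P_H, u, H_i, H_o)
    if (strong) {
      An_o <- added
      J_HA <- 0
    } else {
      fr_o <- 10^(pKa_acid - pH_o); fr_o <- fr_o / (1 + fr_o)
      fr_i <- 10^(pKa_acid - pH_i); fr_i <- fr_i / (1 + fr_i)
      C_tot_o <- added / (1 - fr_o)
      An_o <- C_tot_o * (1 - fr_o)
      J_HA <- P_HA * (C_tot_o * fr_o - y[5] * fr_i)
    }
    # anion (valence -1): equivalent to a cation in the reversed potential
    J_An <- ghk1(P_An, -u, y[4], An_o)

    beta <- ln10 * (H_i + Kw / H_i + sum(C_buf * Ka_buf * H_i / (Ka_buf + H_i)^2))
    dcum <- (J_H + J_HA) * A_over_V
    dpH_i <- -dcum / beta
    ddpsi <- if (clamp) 0 else Fc * (J_H - J_An) / C_spec
    list(c(dpH_i, dcum, ddpsi, J_An * A_over_V, J_HA * A_over_V),
         J_Hplus = J_H, J_HA = J_HA, J_anion = J_An)
  }

  times <- seq(0, config$duration, by = config$dt)
  y0 <- c(pH_i = config$external$pH_initial, cum = 0, dpsi = 0,
          An_i = 0, FA_i = 0)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")

  keep <- which(abs((times / config$record_interval) -
                      round(times / config$record_interval)) < 1e-9)
  out <- data.frame(
    vesicle_id = config$vesicle_id,
    times = sol[keep, "time"],
    pH_o = external_ph(sol[keep, "time"], config$external),
    pH_i = sol[keep, "pH_i"],
    dpsi = if (config$clamp_potential) 0 else sol[keep, "dpsi"],
    J_Hplus = sol[keep, "J_Hplus"],
    J_HA = sol[keep, "J_HA"],
    J_anion = sol[keep, "J_anion"],
    cum_protons = sol[keep, "cum"]
  )
  rownames(out) <- NULL
  attr(out, "radius") <- config$radius
  attr(out, "config") <- config
  class(out) <- c("guv_trace", "data.frame")
  out
}

#' Simulate a cohort of vesicles
#'
#' Draws vesicle radii from a log-normal distribution around the base
#' configuration's radius (CV ~ 15%, matching the dispersion of
#' microfluidically produced GUVs) and simulates each vesicle with the same
#' membrane parameters.
#'
#' @param n Number of vesicles.
#' @param config Base [simulation_config()].
#' @param seed Integer seed for the radius draw (required).
#' @param radius_cv Coefficient of variation of the radius draw. Default 0.15.
#' @return List of `guv_trace` objects with vesicle IDs `1:n`.
#' @export
simulate_cohort <- function(n, config = simulation_config(), seed,
                            radius_cv = 0.15) {
  if (missing(seed) || is.null(seed)) {
    stop("simulate_cohort: an explicit integer seed is required")
  }
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + radius_cv^2))
  radii <- config$radius * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$radius <- radii[i]
    cfg$vesicle_id <- i
    simulate_acidification(cfg)
  })
}

#' Calibrate the mechanistic neutral-acid permeability
#'
#' The field reports weak-acid permeabilities as effective flux-vs-gradient
#' slopes `J / Delta[H+]`, whereas the forward model's `P_HA` multiplies the
#' neutral-form gradient `Delta[HA]`. This helper runs the forward model with
#' the potential clamped and a unit `P_HA`, regresses the ground-truth
#' neutral-acid flux on the ground-truth proton gradient over the early
#' (linear) segment, and scales `P_HA` so that the effective slope equals
#' `target_ratio` times `P_Hplus`. Only forward-model ground truth is used:
#' no image rendering or analysis-pipeline estimate enters the calibration.
#'
#' @param target_ratio Desired effective neutral/ionic slope ratio
#'   (e.g. 4 for formic acid).
#' @param config A [simulation_config()] whose `acid` is a weak acid.
#' @param gradient_fraction Small-gradient segment used to define the
#'   effective slope, as in [fit_permeability_linear()]. Default 0.25.
#' @return The calibrated `P_HA` in cm/s.
#' @export
calibrate_neutral_permeability <- function(target_ratio, config,
                                           gradient_fraction = 0.25) {
  stopifnot(is.finite(config$acid$pKa))
  probe <- config
  probe$acid$P_HA <- 1e-3
  probe$clamp_potential <- TRUE
  tr <- simulate_acidification(probe)
  on_course <- tr$pH_o < config$external$pH_initial - 0.02
  dH <- 10^(-tr$pH_o) / 1000 - 10^(-tr$pH_i) / 1000
  # effective slopes are defined on the linear (small-gradient) regime,
  # matching the analysis-side fit window
  use <- on_course & dH > 0 & dH <= gradient_fraction * max(dH[on_course])
  if (sum(use) < 3) stop("calibrate_neutral_permeability: course too short")
  slope_per_PHA <- sum(tr$J_HA[use] * dH[use]) / sum(dH[use]^2) / probe$acid$P_HA
  target_ratio * config$P_Hplus / slope_per_PHA
}
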