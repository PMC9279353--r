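#' Cumulative concentration of permeated protons
#'
#' Converts a lumenal pH time series into the total concentration of protons
#' that have entered the vesicle, using the buffer capacity to account for
#' the protons absorbed by the buffer:
#' `[H+]T_in(t) = sum beta(pH_mid) * (pH_i(t) - pH_i(t+1))` over consecutive
#' frames, with beta evaluated at the interval midpoint pH. Starts at zero
#' and increases while the lumen acidifies.
#'
#' @param pH_i Lumenal pH series (>= 2 frames).
#' @param buffer A [buffer_system()] or tabulated beta curve.
#' @return Cumulative permeated-proton concentration, mol/cm^3, same length
#'   as `pH_i`, first element 0.
#' @export
cumulative_permeated_protons <- function(pH_i, buffer) {
  if (length(pH_i) < 2) {
    stop("cumulative_permeated_protons: at least 2 frames are required")
  }
  mid <- (pH_i[-length(pH_i)] + pH_i[-1]) / 2
  steps <- buffer_capacity(mid, buffer) * (-diff(pH_i))
  c(0, cumsum(steps))
}

#' Savitzky-Golay smoothing of a time series
#'
#' Local least-squares polynomial smoothing over a moving window. A
#' polynomial of degree <= `order` is reproduced exactly, including at the
#' series ends (asymmetric end-point filters).
#'
#' @param y Numeric series.
#' @param window Odd window length, `order < window <= length(y)`.
#'   Default 15.
#' @param order Polynomial order >= 1. Default 2.
#' @return Smoothed series of the same length.
#' @export
smooth_series <- function(y, window = 15, order = 2) {
  if (window %% 2 == 0) stop("smooth_series: window must be odd")
  if (order < 1 || window <= order) {
    stop("smooth_series: require window > order >= 1")
  }
  if (window > length(y)) stop("smooth_series: window exceeds series length")
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

#' Proton flux density from the cumulative permeation curve
#'
#' `J(t) = d[H+]T_in/dt * (V/A)` with `V/A = r/3` for a sphere, evaluated by
#' central finite differences (one-sided at the ends). Inward-positive.
#'
#' @param cum Cumulative permeated-proton series, mol/cm^3 (smoothed).
#' @param times Strictly increasing time points, s.
#' @param radius Vesicle radius, cm (> 0).
#' @return Flux density series, mol/cm^2/s.
#' @export
compute_flux <- function(cum, times, radius) {
  stopifnot(length(cum) == length(times), radius > 0)
  if (any(diff(times) <= 0)) stop("compute_flux: times must be increasing")
  n <- length(cum)
  if (n < 3) stop("compute_flux: at least 3 frames are required")
  dcum <- numeric(n)
  dcum[2:(n - 1)] <- (cum[3:n] - cum[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
  dcum[1] <- (cum[2] - cum[1]) / (times[2] - times[1])
  dcum[n] <- (cum[n] - cum[n - 1]) / (times[n] - times[n - 1])
  dcum * radius / 3
}

#' Build a per-vesicle flux profile from pH time series
#'
#' Composes [cumulative_permeated_protons()], [smooth_series()] and
#' [compute_flux()] and restricts the result to the analysable window:
#' frames from proton arrival (first frame where the external pH has dropped
#' more than `arrival_drop` below its starting value) until either pH series
#' leaves the resolvable window `(pH_low, pH_high)`. After differentiation,
#' half a smoothing window is trimmed from each end, where the smoother and
#' the finite differences are least reliable.
#'
#' @param times Time points, s.
#' @param pH_i,pH_o Lumenal and external pH series.
#' @param buffer A [buffer_system()].
#' @param radius Vesicle radius, cm.
#' @param vesicle_id Integer ID attached to the profile.
#' @param smooth_window,smooth_order Smoother parameters (see
#'   [smooth_series()]).
#' @param arrival_drop Arrival detection threshold, pH units. Default 0.02.
#' @param pH_low,pH_high Resolvable pH window. Defaults 6.0, 7.6.
#' @param edge_trim Frames trimmed at each end after differentiation;
#'   defaults to half the smoothing window.
#' @return An object of class `flux_profile`: data.frame with columns
#'   `times`, `pH_i`, `pH_o`, `delta_H` (`[H+]_o - [H+]_i`, mol/cm^3), `J`
#'   (mol/cm^2/s), `cum` and `dpH_frame` (per-frame lumenal pH change);
#'   attributes `vesicle_id`, `radius`, `V_over_A`.
#' @export
build_flux_profile <- function(times, pH_i, pH_o, buffer, radius,
                               vesicle_id = 1L, smooth_window = 15,
                               smooth_order = 2, arrival_drop = 0.02,
                               pH_low = 6.0, pH_high = 7.6,
                               edge_trim = NULL) {
  stopifnot(length(times) == length(pH_i), length(pH_i) == length(pH_o))
  baseline <- pH_o[1]
  arrived <- pH_o < baseline - arrival_drop
  resolvable <- pH_i > pH_low & pH_i < pH_high & pH_o > pH_low & pH_o < pH_high
  ok <- arrived & resolvable
  if (!any(ok)) {
    stop("build_flux_profile: no resolvable window after proton arrival")
  }
  # longest contiguous resolvable run (noise can flicker the resolvability
  # flag while the lumen still sits near the saturation bound)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  good <- which(runs$values)
  best <- good[which.max(runs$lengths[good])]
  first <- ends[best] - runs$lengths[best] + 1
  last <- ends[best]
  idx <- first:last
  if (length(idx) < max(smooth_window, 3)) {
    stop("build_flux_profile: resolvable window shorter than the smoothing window")
  }
  t_w <- times[idx]; pHi_w <- pH_i[idx]; pHo_w <- pH_o[idx]
  cum <- cumulative_permeated_protons(pHi_w, buffer)
  cum_s <- smooth_series(cum, smooth_window, smooth_order)
  J <- compute_flux(cum_s, t_w, radius)
  delta_H <- 10^(-pHo_w) / 1000 - 10^(-pHi_w) / 1000
  dpH_frame <- c(abs(diff(pHi_w)), NA_real_)

  if (is.null(edge_trim)) edge_trim <- (smooth_window - 1) / 2
  keep <- seq_along(idx)
  if (length(keep) > 2 * edge_trim + 3) {
    keep <- keep[(edge_trim + 1):(length(keep) - edge_trim)]
  }
  out <- data.frame(times = t_w[keep], pH_i = pHi_w[keep], pH_o = pHo_w[keep],
                    delta_H = delta_H[keep], J = J[keep], cum = cum_s[keep],
                    dpH_frame = dpH_frame[keep])
  rownames(out) <- NULL
  attr(out, "vesicle_id") <- as.integer(vesicle_id)
  attr(out, "radius") <- radius
  attr(out, "V_over_A") <- radius / 3
  class(out) <- c("flux_profile", "data.frame")
  out
}

#' Linear-regime permeability fit
#'
#' Pools `(delta_H, J)` points across profiles, restricts them to the linear
#' regime — where the transmembrane potential is still negligible and
#' `J = P * delta_H` — and fits an ordinary least-squares line through the
#' origin. Zero flux at zero gradient is physically forced, hence no
#' intercept.
#'
#' The linear regime is selected by two gates: the per-frame lumenal pH
#' change must be below `dpH_threshold`, and the gradient must lie in the
#' small-gradient segment of each profile (`delta_H` below
#' `gradient_fraction` of that profile's maximum), because the flux
#' saturates below `P * delta_H` once the potential has built up at larger
#' gradients.
#'
#' @param profiles A `flux_profile` or list of them.
#' @param dpH_threshold Linear-regime gate, pH units per frame. Default 0.1.
#' @param gradient_fraction Upper bound on `delta_H` as a fraction of each
#'   profile's maximum gradient. Default 0.25. Set to 1 to disable.
#' @return An object of class `permeability_estimate`: list with `P` (cm/s),
#'   `se`, `n_points`, `dpH_threshold`.
#' @export
fit_permeability_linear <- function(profiles, dpH_threshold = 0.1,
                                    gradient_fraction = 0.25) {
  if (inherits(profiles, "flux_profile")) profiles <- list(profiles)
  pts <- do.call(rbind, lapply(profiles, function(p) {
    keep <- !is.na(p$dpH_frame) & p$dpH_frame < dpH_threshold &
      p$delta_H <= gradient_fraction * max(p$delta_H)
    data.frame(delta_H = p$delta_H[keep], J = p$J[keep])
  }))
  if (is.null(pts) || nrow(pts) < 3) {
    stop("fit_permeability_linear: fewer than 3 points in the linear regime")
  }
  fit <- stats::lm(J ~ 0 + delta_H, data = pts)
  est <- summary(fit)$coefficients
  out <- list(P = unname(est[1, 1]), se = unname(est[1, 2]),
              n_points = nrow(pts), dpH_threshold = dpH_threshold)
  class(out) <- "permeability_estimate"
  out
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat(sprintf("Permeability estimate: P = %.3g +/- %.3g cm/s (n = %d points)\n",
              x$P, x$se, x$n_points))
  invisible(x)
}

#' Transmembrane potential and pmf from a flux profile
#'
#' GHK inversion of a measured flux profile: for every retained frame, solves
#' the GHK flux equation for the transmembrane potential with `dpsi` as the
#' only free parameter, then computes the proton motive force.
#'
#' @param profile A `flux_profile`.
#' @param P Permeability used for the inversion, cm/s (typically the
#'   vesicle's linear-regime estimate).
#' @param temperature Temperature, K.
#' @param bracket Root bracket in V. Default +/- 0.3.
#' @return data.frame `times`, `dpsi` (V), `pmf` (V), `dpH` as in
#'   [potential_trace()].
#' @export
profile_potential <- function(profile, P, temperature = 294.15,
                              bracket = c(-0.3, 0.3)) {
  stopifnot(inherits(profile, "flux_profile"))
  H_i <- 10^(-profile$pH_i) / 1000
  H_o <- 10^(-profile$pH_o) / 1000
  dpsi <- invert_ghk(profile$J, P, H_i, H_o, temperature, bracket)
  potential_trace(profile$times, dpsi, profile$pH_i, profile$pH_o, temperature)
}

#' Charging-aware GHK permeability fit (strong acids)
#'
#' When the lumen dye is saturated at assay start, the early small-gradient
#' frames of a profile are unmeasurable and the plain linear-regime fit has
#' little or no data before the transmembrane potential has built up. For a
#' strong acid every permeated proton carries charge, so the potential can
#' be reconstructed from the measured cumulative curve itself:
#' \deqn{\Delta\psi(t) = k\,([H^+]^T_{in,0} + [H^+]^T_{in}(t)),\quad
#'   k = \frac{F r}{3 C}}
#' with `C` the effective areal capacitance and the offset term the protons
#' permeated before the profile window opens (recovered from the lumenal pH
#' at window start via the buffer titration function). `P` and `k` are then
#' fitted jointly by least squares of the GHK flux against the measured
#' flux over the whole profile. Not applicable to weak acids, where part of
#' the proton load crosses as a neutral species and carries no charge.
#'
#' @param profile A `flux_profile`.
#' @param buffer The [buffer_system()] used for proton accounting.
#' @param pH_start Lumenal pH at assay start (before acid addition), used to
#'   reconstruct the pre-window permeated amount. Default 7.6.
#' @param temperature Temperature, K.
#' @return An object of class `permeability_estimate` with additional
#'   elements `k` (V cm^3/mol) and `C_spec_eff` (F/cm^2).
#' @export
fit_permeability_ghk <- function(profile, buffer, pH_start = 7.6,
                                 temperature = 294.15) {
  stopifnot(inherits(profile, "flux_profile"))
  if (nrow(profile) < 5) {
    stop("fit_permeability_ghk: profile too short")
  }
  r <- attr(profile, "radius")
  cum0 <- max(titration_acid_added(profile$pH_i[1], buffer, pH_start), 0)
  cum <- cum0 + (profile$cum - profile$cum[1])
  H_i <- 10^(-profile$pH_i) / 1000
  H_o <- 10^(-profile$pH_o) / 1000
  J <- profile$J
  Jscale <- stats::median(abs(J))
  if (!is.finite(Jscale) || Jscale == 0) Jscale <- 1
  obj <- function(par) {
    sum(((ghk_flux(exp(par[1]), exp(par[2]) * cum, H_i, H_o, temperature) -
            J) / Jscale)^2)
  }
  P0 <- stats::median(J / profile$delta_H)
  if (!is.finite(P0) || P0 <= 0) P0 <- 1e-3
  cst <- phys_constants(temperature)
  k0 <- cst$F_const * r / (3 * 1e-3)
  o <- stats::optim(c(log(P0), log(k0)), obj, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  P <- exp(o$par[1]); k <- exp(o$par[2])
  out <- list(P = P, se = NA_real_, n_points = nrow(profile),
              dpH_threshold = NA_real_, k = k,
              C_spec_eff = cst$F_const * r / (3 * k))
  class(out) <- "permeability_estimate"
  out
}
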