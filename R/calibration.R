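#' Pyranine intensity-pH calibration curve
#'
#' Single-site titration model of pyranine (HPTS) fluorescence: intensity
#' rises sigmoidally with pH around an apparent pKa and saturates at the
#' fully deprotonated level. The dye is completely quenched below pH ~6 and
#' saturated above ~7.6, so lumenal and background pH are only resolvable
#' inside `[pH_low, pH_high]`.
#'
#' @param apparent_pKa Apparent pKa of the dye, pH units. Default 7.3.
#' @param I_min Intensity at full quench (arbitrary units). Default 0.
#' @param I_max Intensity at full deprotonation. Default 1000.
#' @param pH_low,pH_high Resolvable pH window. Defaults 6.0 and 7.6.
#' @return An object of class `calibration_curve`.
#' @examples
#' crv <- calibration_curve()
#' ph_to_intensity(7.3, crv)
#' @export
calibration_curve <- function(apparent_pKa = 7.3, I_min = 0, I_max = 1000,
                              pH_low = 6.0, pH_high = 7.6) {
  stopifnot(I_max > I_min, I_min >= 0,
            pH_low > 0, pH_high < 14, pH_low < pH_high)
  structure(
    list(apparent_pKa = apparent_pKa, I_min = I_min, I_max = I_max,
         pH_low = pH_low, pH_high = pH_high),
    class = "calibration_curve"
  )
}

#' Map pH to pyranine fluorescence intensity
#'
#' @param pH pH values (finite). Vectorised.
#' @param curve A [calibration_curve()] or [tabulated_curve()].
#' @return Intensity in the curve's arbitrary units; strictly increasing in pH.
#' @export
ph_to_intensity <- function(pH, curve) UseMethod("ph_to_intensity", curve)

#' @export
ph_to_intensity.calibration_curve <- function(pH, curve) {
  if (!all(is.finite(pH))) stop("ph_to_intensity: pH must be finite")
  curve$I_min + (curve$I_max - curve$I_min) / (1 + 10^(curve$apparent_pKa - pH))
}

#' Invert a calibration curve: intensity to pH
#'
#' Exact algebraic inverse of [ph_to_intensity()]. Values that fall outside
#' the resolvable window `[pH_low, pH_high]` are still computed but flagged:
#' the returned vector carries a logical attribute `"resolvable"` (see
#' [is_resolvable()]). Intensities at or beyond the quench/saturation bounds
#' have no finite inverse and raise an error.
#'
#' @param I Intensity, strictly between `I_min` and `I_max`. Vectorised.
#' @param curve A [calibration_curve()] or [tabulated_curve()].
#' @return Numeric pH vector with attribute `resolvable`.
#' @export
intensity_to_ph <- function(I, curve) UseMethod("intensity_to_ph", curve)

#' @export
intensity_to_ph.calibration_curve <- function(I, curve) {
  if (any(I <= curve$I_min)) {
    stop("intensity_to_ph: intensity at or below the full-quench bound I_min; ",
         "pH cannot be resolved below the quench point")
  }
  if (any(I >= curve$I_max)) {
    stop("intensity_to_ph: intensity at or above the saturation bound I_max; ",
         "pH cannot be resolved above the saturation point")
  }
  frac <- (I - curve$I_min) / (curve$I_max - curve$I_min)
  pH <- curve$apparent_pKa - log10(1 / frac - 1)
  attr(pH, "resolvable") <- pH > curve$pH_low & pH < curve$pH_high
  pH
}

#' Resolvability flag of an inverted pH estimate
#'
#' @param pH Result of [intensity_to_ph()].
#' @return Logical vector: TRUE where the estimate lies inside the curve's
#'   resolvable window.
#' @export
is_resolvable <- function(pH) {
  r <- attr(pH, "resolvable")
  if (is.null(r)) stop("is_resolvable: no resolvable attribute present")
  r
}

#' Tabulated calibration or buffer-capacity curve
#'
#' Reads a two-column CSV (first column pH, second column value: intensity or
#' buffer capacity) and interpolates linearly between rows. Used to substitute
#' a measured calibration or beta(pH) curve for the analytic defaults.
#'
#' @param path Path to a two-column CSV with a header row.
#' @param pH_low,pH_high Resolvable window for calibration use; defaults to
#'   the tabulated pH range.
#' @return An object of class `tabulated_curve`.
#' @examples
#' p <- system.file("extdata", "pyranine_calibration_synthetic.csv",
#'                  package = "guvflux")
#' crv <- tabulated_curve(p, pH_low = 6, pH_high = 7.6)
#' ph_to_intensity(7.2, crv)
#' @export
tabulated_curve <- function(path, pH_low = NULL, pH_high = NULL) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L) stop("tabulated_curve: expected two columns (pH, value)")
  tab <- tab[order(tab[[1]]), ]
  structure(
    list(pH = tab[[1]], value = tab[[2]],
         pH_low = if (is.null(pH_low)) min(tab[[1]]) else pH_low,
         pH_high = if (is.null(pH_high)) max(tab[[1]]) else pH_high),
    class = "tabulated_curve"
  )
}

#' @export
ph_to_intensity.tabulated_curve <- function(pH, curve) {
  if (!all(is.finite(pH))) stop("ph_to_intensity: pH must be finite")
  stats::approx(curve$pH, curve$value, xout = pH, rule = 2)$y
}

#' @export
intensity_to_ph.tabulated_curve <- function(I, curve) {
  rng <- range(curve$value)
  if (any(I <= rng[1]) || any(I >= rng[2])) {
    stop("intensity_to_ph: intensity outside the tabulated range; ",
         "pH cannot be resolved beyond the quench/saturation bounds")
  }
  pH <- stats::approx(curve$value, curve$pH, xout = I)$y
  attr(pH, "resolvable") <- pH > curve$pH_low & pH < curve$pH_high
  pH
}

#' Buffer system
#'
#' One or more weak-acid buffer components plus water autoionisation.
#' Concentrations are mol/cm^3 internally (10 mM = 1e-5 mol/cm^3).
#'
#' @param components data.frame with columns `name`, `pKa` and `conc`
#'   (total concentration, mol/cm^3).
#' @param temperature Temperature in K.
#' @return An object of class `buffer_system`.
#' @examples
#' hepes_buffer()
#' @export
buffer_system <- function(components, temperature = 294.15) {
  stopifnot(is.data.frame(components),
            all(c("name", "pKa", "conc") %in% names(components)))
  if (nrow(components) > 0) {
    stopifnot(all(components$conc > 0), all(is.finite(components$pKa)))
  }
  structure(list(components = components, temperature = temperature),
            class = "buffer_system")
}

#' HEPES buffer preset
#'
#' 10 mM HEPES at 21 degC, the lumenal and external buffer of the acid
#' addition assay (sucrose/glucose osmolytes do not buffer and are omitted).
#' HEPES pKa defaults to 7.5 near 21 degC.
#'
#' @param conc Total HEPES concentration, mol/cm^3. Default 1e-5 (10 mM).
#' @param pKa HEPES pKa. Default 7.5.
#' @param temperature Temperature in K.
#' @return A [buffer_system()].
#' @export
hepes_buffer <- function(conc = 1e-5, pKa = 7.5, temperature = 294.15) {
  buffer_system(
    data.frame(name = "HEPES", pKa = pKa, conc = conc),
    temperature = temperature
  )
}

#' Buffer capacity beta(pH)
#'
#' Moles of strong acid per unit volume needed to lower the pH by one unit:
#' \deqn{\beta = \ln(10)\left([H^+] + \frac{K_w}{[H^+]} +
#'   \sum_i C_i \frac{K_{a,i} [H^+]}{(K_{a,i} + [H^+])^2}\right)}
#' with all concentrations in mol/cm^3. An empty buffer gives the water-only
#' capacity.
#'
#' @param pH pH in (0, 14). Vectorised.
#' @param buffer A [buffer_system()] or a [tabulated_curve()] of measured
#'   beta values.
#' @return beta in mol/cm^3 per pH unit (> 0).
#' @examples
#' buffer_capacity(7.5, hepes_buffer())
#' @export
buffer_capacity <- function(pH, buffer) UseMethod("buffer_capacity", buffer)

#' @export
buffer_capacity.buffer_system <- function(pH, buffer) {
  stopifnot(all(pH > 0), all(pH < 14))
  cst <- phys_constants(buffer$temperature)
  H <- 10^(-pH) / 1000
  beta <- H + cst$Kw / H
  if (nrow(buffer$components) > 0) {
    for (i in seq_len(nrow(buffer$components))) {
      Ka <- 10^(-buffer$components$pKa[i]) / 1000
      C <- buffer$components$conc[i]
      beta <- beta + C * Ka * H / (Ka + H)^2
    }
  }
  log(10) * beta
}

#' @export
buffer_capacity.tabulated_curve <- function(pH, buffer) {
  stats::approx(buffer$pH, buffer$value, xout = pH, rule = 2)$y
}

#' Strong-acid equivalents needed to titrate a buffer to a given pH
#'
#' Closed-form titration function: the amount of strong acid (mol/cm^3) that
#' must be added to move the buffer from `pH_ref` down to `pH`. Its negative
#' derivative with respect to pH is [buffer_capacity()]. Used by the forward
#' simulator to convert an external pH course into the amount (and hence
#' anion concentration) of acid added.
#'
#' @param pH Target pH. Vectorised.
#' @param buffer A [buffer_system()].
#' @param pH_ref Reference (starting) pH.
#' @return Acid added in mol/cm^3 (positive when `pH < pH_ref`).
#' @export
titration_acid_added <- function(pH, buffer, pH_ref) {
  stopifnot(inherits(buffer, "buffer_system"))
  cst <- phys_constants(buffer$temperature)
  net_base <- function(p) {
    # deprotonated buffer + hydroxide - free protons, all mol/cm^3
    H <- 10^(-p) / 1000
    tot <- cst$Kw / H - H
    if (nrow(buffer$components) > 0) {
      for (i in seq_len(nrow(buffer$components))) {
        Ka <- 10^(-buffer$components$pKa[i]) / 1000
        tot <- tot + buffer$components$conc[i] * Ka / (Ka + H)
      }
    }
    tot
  }
  net_base(pH_ref) - net_base(pH)
}
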