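#' Load a simulation configuration from YAML
#'
#' The YAML mirrors the [simulation_config()] fields, with nested `acid`
#' (`name`, `pKa`, `P_HA`, `P_anion`; use `pKa: .inf` negative or omit for a
#' strong acid), `buffer` (list of `{name, pKa, conc}` components plus
#' `temperature`) and `external` (`pH_initial`, `pH_final`, `arrival_time`,
#' `tau`) blocks. Missing fields fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
simulation_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(lst, name, default) {
    if (!is.null(lst[[name]])) lst[[name]] else default
  }
  acid <- if (is.null(y$acid)) strong_acid() else {
    pKa <- grab(y$acid, "pKa", -Inf)
    acid_species(grab(y$acid, "name", "acid"),
                 if (is.null(pKa) || !is.finite(pKa)) -Inf else pKa,
                 P_HA = grab(y$acid, "P_HA", 0),
                 P_anion = grab(y$acid, "P_anion", 1e-10))
  }
  buffer <- if (is.null(y$buffer)) hepes_buffer() else {
    comps <- do.call(rbind, lapply(y$buffer$components, function(cmp) {
      data.frame(name = cmp$name, pKa = cmp$pKa, conc = cmp$conc)
    }))
    buffer_system(comps, temperature = grab(y$buffer, "temperature", 294.15))
  }
  ext <- if (is.null(y$external)) external_course() else {
    external_course(grab(y$external, "pH_initial", 7.6),
                    grab(y$external, "pH_final", 6.9),
                    grab(y$external, "arrival_time", 60),
                    grab(y$external, "tau", 120))
  }
  simulation_config(
    radius = grab(y, "radius", 1e-3),
    P_Hplus = grab(y, "P_Hplus", 1.9e-3),
    acid = acid, buffer = buffer, external = ext,
    C_spec = grab(y, "C_spec", 5e-4),
    dt = grab(y, "dt", 0.05),
    duration = grab(y, "duration", 600),
    record_interval = grab(y, "record_interval", 5),
    clamp_potential = grab(y, "clamp_potential", FALSE),
    seed = grab(y, "seed", NULL)
  )
}
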