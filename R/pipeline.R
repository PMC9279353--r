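TRACE_SCHEMA_HEADER <- "# guvflux traces v1"
TRACKS_SCHEMA_HEADER <- "# guvflux tracks v1"

#' Write / read ground-truth traces CSV
#'
#' Columns: `vesicle_id, t_s, pH_o, pH_i, dpsi_mV, J_Hplus_mol_cm2_s,
#' J_HA_mol_cm2_s, radius_um`. A versioned schema comment is written as the
#' first line. Units are converted at this boundary only (V -> mV,
#' cm -> um); everything in memory stays in mol/cm^3, V, cm.
#'
#' @param traces List of `guv_trace` objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "guv_trace")) traces <- list(traces)
  tab <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(
      vesicle_id = tr$vesicle_id, t_s = tr$times, pH_o = tr$pH_o,
      pH_i = tr$pH_i, dpsi_mV = tr$dpsi * 1000,
      J_Hplus_mol_cm2_s = tr$J_Hplus, J_HA_mol_cm2_s = tr$J_HA,
      radius_um = attr(tr, "radius") * 1e4
    )
  }))
  con <- file(path, "w")
  writeLines(TRACE_SCHEMA_HEADER, con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, TRACE_SCHEMA_HEADER)) {
    stop("read_traces: unrecognised schema; expected '", TRACE_SCHEMA_HEADER, "'")
  }
  utils::read.csv(path, comment.char = "#")
}

#' Write / read measured tracks CSV
#'
#' Columns as produced by [measure_stack()].
#'
#' @param tracks data.frame from [measure_stack()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  con <- file(path, "w")
  writeLines(TRACKS_SCHEMA_HEADER, con)
  utils::write.csv(tracks, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, TRACKS_SCHEMA_HEADER)) {
    stop("read_tracks: unrecognised schema; expected '", TRACKS_SCHEMA_HEADER, "'")
  }
  utils::read.csv(path, comment.char = "#")
}

# lay vesicles out on a grid with a safety margin
grid_positions <- function(n, size, r_px, ring_thickness = 3) {
  margin <- r_px + ring_thickness / 2 + 2
  pitch <- 2 * margin + 4
  per_row <- max(1, floor((size[2] - 2 * margin) / pitch) + 1)
  xy <- t(vapply(seq_len(n) - 1, function(k) {
    c(margin + (k %% per_row) * pitch, margin + (k %/% per_row) * pitch)
  }, numeric(2)))
  if (any(xy[, 1] + margin > size[2] - 1 | xy[, 2] + margin > size[1] - 1)) {
    stop("grid_positions: too many vesicles for the frame")
  }
  xy
}

#' Simulate a cohort and write traces (and optionally rendered stacks)
#'
#' @param outdir Output directory (created if missing).
#' @param n_vesicles Number of vesicles. Default 10.
#' @param config Base [simulation_config()].
#' @param seed Global integer seed; per-stage seeds are derived from it.
#'   Required.
#' @param mode `"trace"` or `"image"`; image mode additionally renders the
#'   cohort and writes two multi-page TIFFs.
#' @param curve [calibration_curve()] used for rendering in image mode.
#' @param img Optional [image_render_config()]; by default vesicles are laid
#'   out on a grid in a 256 x 256 frame at 0.5 um/px.
#' @param radius_cv Radius dispersion of the cohort; 0 renders identical
#'   radii. Default 0.15.
#' @return Invisibly, a list with the traces, the written paths and the
#'   manifest.
#' @export
run_simulate <- function(outdir, n_vesicles = 10, config = simulation_config(),
                         seed = NULL, mode = c("trace", "image"),
                         curve = calibration_curve(), img = NULL,
                         radius_cv = 0.15) {
  mode <- match.arg(mode)
  if (is.null(seed)) stop("run_simulate: an explicit integer seed is required")
  seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  traces <- simulate_cohort(n_vesicles, config, seed = seed,
                            radius_cv = radius_cv)
  paths <- list(traces = file.path(outdir, "traces.csv"))
  write_traces(traces, paths$traces)
  stack <- NULL
  if (mode == "image") {
    if (is.null(img)) {
      r_px_max <- max(vapply(traces, function(tr) attr(tr, "radius"),
                             numeric(1))) * 1e4 / 0.5
      img <- image_render_config(
        size = c(256L, 256L), pixel_size = 0.5,
        frame_interval = config$record_interval,
        positions = grid_positions(n_vesicles, c(256L, 256L), r_px_max),
        seed = seed + 1L
      )
    }
    stack <- render_timelapse(traces, curve, img)
    paths$membrane_tiff <- file.path(outdir, "membrane.tif")
    paths$lumen_tiff <- file.path(outdir, "lumen.tif")
    write_stack_tiff(stack, paths$membrane_tiff, paths$lumen_tiff)
  }
  manifest <- list(
    mode = mode, seed = seed, n_vesicles = n_vesicles,
    traces_md5 = unname(tools::md5sum(paths$traces)),
    parameters = list(
      radius_cm = config$radius, P_Hplus = config$P_Hplus,
      acid = config$acid$name, pKa = config$acid$pKa,
      P_HA = config$acid$P_HA, P_anion = config$acid$P_anion,
      C_spec = config$C_spec, dt = config$dt, duration = config$duration,
      record_interval = config$record_interval,
      clamp_potential = config$clamp_potential,
      pH_initial = config$external$pH_initial,
      pH_final = config$external$pH_final,
      arrival_time = config$external$arrival_time, tau = config$external$tau
    )
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(list(traces = traces, stack = stack, paths = paths,
                 manifest = manifest))
}

#' Analyse traces or an image stack into flux profiles and permeabilities
#'
#' Trace-level mode consumes per-vesicle pH time series directly (bypassing
#' imaging); image-level mode first detects, tracks and measures the stack,
#' then inverts the calibration curve to pH. Both modes then build per-
#' vesicle flux profiles, fit the linear-regime permeability per vesicle and
#' pooled, and invert the GHK equation for the potential / pmf trace.
#'
#' @param input Trace mode: a traces CSV path, a traces data.frame, or a
#'   list of `guv_trace`.
#'   Image mode: a `guv_stack` or `c(membrane, lumen)` TIFF paths.
#' @param mode `"trace"` or `"image"`.
#' @param curve [calibration_curve()] (image mode).
#' @param buffer [buffer_system()] used for proton accounting.
#' @param radius_range Hough search range in px (image mode); default
#'   derived from 5-25 um at the stack's pixel size.
#' @param pixel_size,frame_interval Stack metadata (required when `input`
#'   is a pair of TIFF paths).
#' @param smooth_window,smooth_order,arrival_drop,dpH_threshold Analysis
#'   parameters (see [build_flux_profile()], [fit_permeability_linear()]).
#' @param presmooth Smooth the measured pH series (same window/order) before
#'   profile building; defaults to TRUE in image mode, where the per-frame
#'   intensity noise propagates into pH, and FALSE in trace mode.
#' @param fit_method Per-vesicle permeability estimator:
#'   [fit_permeability_linear()] (`"linear"`, trace-mode default) or the
#'   charging-aware [fit_permeability_ghk()] (`"ghk"`, image-mode default,
#'   strong acids only -- use `"linear"` when analysing weak-acid data).
#' @param P_inversion Permeability used for the GHK potential inversion:
#'   `"vesicle"` (that vesicle's fit, default), `"pooled"`, or a number.
#' @param outdir Optional directory for result CSVs.
#' @param temperature Temperature, K.
#' @return List of class `guv_analysis`: `profiles`, `fits` (per-vesicle
#'   data.frame), `pooled` ([fit_permeability_linear()] result),
#'   `potentials` (per-vesicle pmf traces), `summary`.
#' @export
run_analyze <- function(input, mode = c("trace", "image"),
                        curve = calibration_curve(), buffer = hepes_buffer(),
                        radius_range = NULL, pixel_size = NULL,
                        frame_interval = NULL, smooth_window = 15,
                        smooth_order = 2, arrival_drop = 0.02,
                        dpH_threshold = 0.1, P_inversion = "vesicle",
                        presmooth = NULL, fit_method = NULL, outdir = NULL,
                        temperature = 294.15) {
  mode <- match.arg(mode)
  if (is.null(presmooth)) presmooth <- mode == "image"
  if (is.null(fit_method)) fit_method <- if (mode == "image") "ghk" else "linear"
  fit_method <- match.arg(fit_method, c("linear", "ghk"))
  if (mode == "trace") {
    tab <- if (is.character(input)) read_traces(input)
    else if (is.data.frame(input)) input
    else {
      do.call(rbind, lapply(input, function(tr) {
        data.frame(vesicle_id = tr$vesicle_id, t_s = tr$times,
                   pH_o = tr$pH_o, pH_i = tr$pH_i,
                   radius_um = attr(tr, "radius") * 1e4)
      }))
    }
  } else {
    stack <- if (inherits(input, "guv_stack")) input else {
      if (length(input) != 2) {
        stop("run_analyze: image mode expects a guv_stack or two TIFF paths")
      }
      read_stack_tiff(input[1], input[2], pixel_size, frame_interval)
    }
    px <- attr(stack, "pixel_size")
    if (is.null(radius_range)) {
      radius_range <- c(max(4, floor(5 / px)), ceiling(25 / px))
    }
    tracks <- measure_stack(stack, radius_range)
    pH_i <- intensity_to_ph(tracks$lumen_intensity, curve)
    pH_o <- intensity_to_ph(tracks$background_intensity, curve)
    tab <- data.frame(vesicle_id = tracks$vesicle_id, t_s = tracks$t_s,
                      pH_o = as.numeric(pH_o), pH_i = as.numeric(pH_i),
                      radius_um = tracks$radius_um)
  }
  if (nrow(tab) == 0) stop("run_analyze: empty input")
  need <- c("vesicle_id", "t_s", "pH_o", "pH_i", "radius_um")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("run_analyze: input is missing column(s): ", paste(miss, collapse = ", "))
  }

  ids <- sort(unique(tab$vesicle_id))
  profiles <- list(); potentials <- list()
  fit_rows <- list()
  for (id in ids) {
    sub <- tab[tab$vesicle_id == id, ]
    sub <- sub[order(sub$t_s), ]
    radius_cm <- stats::median(sub$radius_um) * 1e-4
    if (presmooth && nrow(sub) >= smooth_window) {
      sub$pH_i <- smooth_series(sub$pH_i, smooth_window, smooth_order)
      sub$pH_o <- smooth_series(sub$pH_o, smooth_window, smooth_order)
    }
    prof <- tryCatch(
      build_flux_profile(sub$t_s, sub$pH_i, sub$pH_o, buffer, radius_cm,
                         vesicle_id = id, smooth_window = smooth_window,
                         smooth_order = smooth_order,
                         arrival_drop = arrival_drop),
      error = function(e) NULL
    )
    if (is.null(prof)) next
    fit <- tryCatch(
      if (fit_method == "ghk") {
        pH_start <- stats::median(sub$pH_i[seq_len(min(5, nrow(sub)))])
        fit_permeability_ghk(prof, buffer, pH_start, temperature)
      } else {
        fit_permeability_linear(prof, dpH_threshold)
      },
      error = function(e) NULL)
    profiles[[as.character(id)]] <- prof
    fit_rows[[as.character(id)]] <- data.frame(
      vesicle_id = id, radius_um = radius_cm * 1e4,
      P = if (is.null(fit)) NA_real_ else fit$P,
      se = if (is.null(fit)) NA_real_ else fit$se,
      n_points = if (is.null(fit)) 0L else fit$n_points
    )
  }
  if (length(profiles) == 0) {
    stop("run_analyze: no vesicle yielded an analysable flux profile")
  }
  fits <- do.call(rbind, fit_rows)
  rownames(fits) <- NULL
  pooled <- tryCatch(fit_permeability_linear(profiles, dpH_threshold),
                     error = function(e) {
                       est <- list(P = stats::median(fits$P, na.rm = TRUE),
                                   se = NA_real_,
                                   n_points = sum(fits$n_points),
                                   dpH_threshold = dpH_threshold)
                       class(est) <- "permeability_estimate"
                       est
                     })

  for (id in names(profiles)) {
    P_inv <- if (is.numeric(P_inversion)) P_inversion
      else if (identical(P_inversion, "pooled")) pooled$P
      else fits$P[fits$vesicle_id == as.integer(id)]
    if (!is.finite(P_inv) || P_inv <= 0) P_inv <- pooled$P
    potentials[[id]] <- tryCatch(
      cbind(vesicle_id = as.integer(id),
            profile_potential(profiles[[id]], P_inv, temperature)),
      error = function(e) NULL
    )
  }
  potentials <- potentials[!vapply(potentials, is.null, logical(1))]

  pmf_max <- if (length(potentials) > 0) {
    pot <- do.call(rbind, potentials)
    agg <- stats::aggregate(pmf ~ times, pot, mean)
    max(agg$pmf)
  } else NA_real_
  summary <- data.frame(
    n_vesicles = length(profiles),
    P_mean = mean(fits$P, na.rm = TRUE),
    P_median = stats::median(fits$P, na.rm = TRUE),
    P_pooled = pooled$P,
    pmf_max_mean_mV = pmf_max * 1000
  )

  out <- list(profiles = profiles, fits = fits, pooled = pooled,
              potentials = potentials, summary = summary)
  class(out) <- "guv_analysis"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fits, file.path(outdir, "permeability_fits.csv"),
                     row.names = FALSE)
    prof_tab <- do.call(rbind, lapply(profiles, function(p) {
      cbind(vesicle_id = attr(p, "vesicle_id"), as.data.frame(p))
    }))
    utils::write.csv(prof_tab, file.path(outdir, "flux_profiles.csv"),
                     row.names = FALSE)
    if (length(potentials) > 0) {
      pot_tab <- do.call(rbind, potentials)
      pot_tab$dpsi_mV <- pot_tab$dpsi * 1000
      pot_tab$pmf_mV <- pot_tab$pmf * 1000
      utils::write.csv(
        pot_tab[, c("vesicle_id", "times", "dpsi_mV", "pmf_mV", "dpH")],
        file.path(outdir, "potential_traces.csv"), row.names = FALSE)
    }
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.guv_analysis <- function(x, ...) {
  cat(sprintf(
    "GUV flux analysis: %d vesicles\n  median P = %.3g cm/s, pooled P = %.3g cm/s\n  max mean pmf = %.3g mV\n",
    x$summary$n_vesicles, x$summary$P_median, x$summary$P_pooled,
    x$summary$pmf_max_mean_mV))
  invisible(x)
}

#' Parameter-recovery harness
#'
#' Simulates a cohort with known permeability, runs the trace-level (or
#' image-level) analysis, and reports recovered-vs-true permeability and,
#' for unclamped runs, the error of the GHK-inverted potential against the
#' simulator's ground truth (inverted with the true P, frame-matched).
#'
#' @param seed Integer seed. Required.
#' @param n_vesicles Cohort size. Default 10.
#' @param config Base [simulation_config()].
#' @param mode `"trace"` or `"image"`.
#' @param ... Passed to [run_analyze()].
#' @return List with `P_true`, `P_median`, `P_rel_error`, `analysis`,
#'   `dpsi_max_error_V` (max over retained frames and vesicles), `traces`.
#' @export
run_recover <- function(seed, n_vesicles = 10, config = simulation_config(),
                        mode = c("trace", "image"), ...) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("run_recover: an explicit integer seed is required")
  traces <- simulate_cohort(n_vesicles, config, seed = seed)
  if (mode == "trace") {
    analysis <- run_analyze(traces, mode = "trace", buffer = config$buffer,
                            temperature = config$buffer$temperature, ...)
  } else {
    curve <- calibration_curve()
    r_px_max <- max(vapply(traces, function(tr) attr(tr, "radius"),
                           numeric(1))) * 1e4 / 0.5
    img <- image_render_config(
      size = c(256L, 256L), pixel_size = 0.5,
      frame_interval = config$record_interval,
      positions = grid_positions(n_vesicles, c(256L, 256L), r_px_max),
      seed = seed + 1L
    )
    stack <- render_timelapse(traces, curve, img)
    analysis <- run_analyze(stack, mode = "image", curve = curve,
                            buffer = config$buffer,
                            temperature = config$buffer$temperature, ...)
  }
  P_med <- analysis$summary$P_median

  dpsi_err <- NA_real_
  if (!config$clamp_potential && mode == "trace") {
    errs <- c()
    for (id in names(analysis$profiles)) {
      prof <- analysis$profiles[[id]]
      tr <- traces[[as.integer(id)]]
      pot <- profile_potential(prof, config$P_Hplus,
                               config$buffer$temperature)
      truth <- tr$dpsi[match(round(prof$times, 6), round(tr$times, 6))]
      errs <- c(errs, abs(pot$dpsi - truth))
    }
    dpsi_err <- max(errs)
  }
  list(P_true = config$P_Hplus, P_median = P_med,
       P_rel_error = abs(P_med - config$P_Hplus) / config$P_Hplus,
       dpsi_max_error_V = dpsi_err, analysis = analysis, traces = traces)
}

#' Weak-acid decomposition from strong- and weak-acid cohorts
#'
#' Runs the full decomposition procedure: fits the pooled linear-regime
#' effective permeability of a weak-acid cohort (protons arriving as both
#' H+ and neutral acid) and of a strong-acid cohort (H+ only), and
#' subtracts.
#'
#' @param analysis_weak,analysis_strong `guv_analysis` objects from
#'   [run_analyze()].
#' @return A [decompose_weak_acid()] result.
#' @export
decompose_cohorts <- function(analysis_weak, analysis_strong) {
  decompose_weak_acid(analysis_weak$pooled$P, analysis_strong$pooled$P)
}

#' Reference mean proton permeabilities by membrane composition
#'
#' Literature mean permeability coefficients used as simulator presets:
#' charged DOPC:DOPG (3:1) GUVs and uncharged DOPC GUVs measured under
#' identical strong-acid assay conditions. The charged membranes pass
#' protons about twice as fast, reflecting surface-potential-enhanced
#' interfacial proton concentration; the solvation barrier remains the
#' dominant resistance.
#'
#' @return data.frame with columns `composition` and `P_mean` (cm/s).
#' @export
lipid_permeability_reference <- function() {
  data.frame(
    composition = c("PC:PG", "PC"),
    P_mean = c(1.9e-3, 8.3e-4)
  )
}
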