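test_that("cumulative proton accounting handles the base cases", {
  buf <- hepes_buffer()
  expect_equal(cumulative_permeated_protons(rep(7.3, 5), buf), rep(0, 5))
  # single step with a known constant beta
  flat <- tabulated_curve_from <- NULL
  beta_tab <- structure(list(pH = c(0, 14), value = c(5e-6, 5e-6),
                             pH_low = 0, pH_high = 14),
                        class = "tabulated_curve")
  expect_equal(cumulative_permeated_protons(c(7.60, 7.50), beta_tab),
               c(0, 5e-7))
  expect_error(cumulative_permeated_protons(7.3, buf), "2 frames")
  # accounting identity: the end value is exactly the summed increments
  pH <- 7.6 - cumsum(c(0, runif(20, 0, 0.01)))
  cum <- cumulative_permeated_protons(pH, buf)
  mid <- (pH[-21] + pH[-1]) / 2
  expect_equal(cum[21], sum(buffer_capacity(mid, buf) * (-diff(pH))))
})

test_that("the smoother reproduces low-order polynomials exactly", {
  x <- seq_len(50)
  lin <- 2 + 0.3 * x
  expect_equal(smooth_series(lin, 15, 2), lin, tolerance = 1e-12)
  expect_equal(smooth_series(rep(4, 30), 7, 2), rep(4, 30))
  quad <- 1 + 0.1 * x - 0.02 * x^2
  expect_equal(smooth_series(quad, 11, 2), quad, tolerance = 1e-9)
  expect_error(smooth_series(lin, 14, 2), "odd")
  expect_error(smooth_series(lin, 5, 5), "order")
  expect_error(smooth_series(lin[1:5], 15, 2), "length")
})

test_that("smoothing reduces noise around a known curve", {
  set.seed(42)
  x <- seq_len(200)
  truth <- 5e-7 * (x / 200)^2
  noisy <- truth + rnorm(200, 0, 2e-8)
  sm <- smooth_series(noisy, 15, 2)
  expect_lt(sqrt(mean((sm - truth)^2)), sqrt(mean((noisy - truth)^2)) / 2)
})

test_that("flux from the cumulative curve follows the definitions", {
  times <- seq(0, 100, by = 5)
  expect_equal(compute_flux(rep(1e-7, 21), times, 1e-3), rep(0, 21))
  # linear ramp: J = k * r / 3 everywhere
  k <- 2e-9
  expect_equal(compute_flux(k * times, times, 1e-3), rep(k * 1e-3 / 3, 21))
  expect_error(compute_flux(1:5, c(1, 2, 2, 3, 4), 1e-3), "increasing")
})

test_that("clamped simulation round-trips through the flux pipeline", {
  cfg <- simulation_config(clamp_potential = TRUE, duration = 600)
  tr <- simulate_acidification(cfg)
  prof <- build_flux_profile(tr$times, tr$pH_i, tr$pH_o, cfg$buffer,
                             cfg$radius)
  # recovered flux matches the simulated ground truth away from edges
  truth <- tr$J_Hplus[match(prof$times, tr$times)]
  expect_equal(prof$J, truth, tolerance = 0.02)
  # profile is linear in delta_H: J = P * delta_H
  fit <- lm(J ~ 0 + delta_H, data = prof)
  expect_gt(summary(fit)$r.squared, 0.999)
  # cumulative curve matches the simulator bookkeeping within 1%
  end_truth <- tr$cum_protons[match(max(prof$times), tr$times)]
  start_truth <- tr$cum_protons[match(min(prof$times), tr$times)]
  expect_equal(max(prof$cum) - min(prof$cum), end_truth - start_truth,
               tolerance = 0.01)
})

test_that("profile building trims unresolvable and pre-arrival frames", {
  buf <- hepes_buffer()
  times <- seq(0, 500, by = 5)
  # pre-arrival only: flat external pH -> no window
  expect_error(
    build_flux_profile(times, rep(7.5, 101), rep(7.6, 101), buf, 1e-3),
    "no resolvable window")
  # external pH crossing the quench bound ends the profile
  pH_o <- seq(7.5, 5.6, length.out = 101)
  pH_i <- seq(7.55, 7.0, length.out = 101)
  prof <- build_flux_profile(times, pH_i, pH_o, buf, 1e-3,
                             edge_trim = 0)
  k <- max(which(pH_o > 6))
  expect_lte(nrow(prof), k)
  expect_true(all(prof$pH_o > 6))
})

test_that("linear fits recover exact slopes and enforce the regime gates", {
  mk <- function(dH, J, dpH = 1e-3) {
    structure(data.frame(times = seq_along(dH), pH_i = 7.3, pH_o = 7.0,
                         delta_H = dH, J = J, cum = cumsum(J),
                         dpH_frame = dpH),
              class = c("flux_profile", "data.frame"),
              vesicle_id = 1L, radius = 1e-3, V_over_A = 1e-3 / 3)
  }
  dH <- seq(1e-12, 1e-10, length.out = 30)
  # suppress summary.lm's "essentially perfect fit" note: exactness is the point
  fit <- suppressWarnings(
    fit_permeability_linear(mk(dH, 2e-3 * dH), gradient_fraction = 1))
  expect_equal(fit$P, 2e-3, tolerance = 1e-12)
  expect_lt(fit$se, 1e-15)
  # all points beyond the per-frame dpH gate -> error
  expect_error(fit_permeability_linear(mk(dH, 2e-3 * dH, dpH = 0.5)),
               "fewer than 3")
  # the small-gradient gate drops saturated large-gradient points
  J_sat <- 2e-3 * dH * (1 - 0.5 * dH / max(dH))
  fit_sat <- fit_permeability_linear(mk(dH, J_sat), gradient_fraction = 0.25)
  expect_equal(fit_sat$P, 2e-3, tolerance = 0.15)
})

test_that("trace-level permeability recovery is unbiased across seeds", {
  errs <- vapply(1:8, function(s) {
    rec <- run_recover(seed = s, n_vesicles = 1,
                       config = simulation_config())
    rec$P_rel_error
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("flux saturation is detectable in unclamped strong-acid runs", {
  cfg <- simulation_config(acid = strong_acid(P_anion = 0), duration = 600)
  tr <- simulate_acidification(cfg)
  prof <- build_flux_profile(tr$times, tr$pH_i, tr$pH_o, cfg$buffer,
                             cfg$radius)
  i <- which.max(prof$delta_H)
  expect_lt(prof$J[i] / (cfg$P_Hplus * prof$delta_H[i]), 0.9)
})

test_that("GHK inversion of an analysed profile recovers the potential", {
  cfg <- simulation_config(duration = 600)
  tr <- simulate_acidification(cfg)
  prof <- build_flux_profile(tr$times, tr$pH_i, tr$pH_o, cfg$buffer,
                             cfg$radius)
  pot <- profile_potential(prof, cfg$P_Hplus)
  truth <- tr$dpsi[match(prof$times, tr$times)]
  expect_lt(max(abs(pot$dpsi - truth)), 0.5e-3)
  expect_equal(pot$pmf, pmf(pot$dpsi, prof$pH_i, prof$pH_o))
})

test_that("charging-aware fit matches the linear fit on clean traces", {
  cfg <- simulation_config(duration = 600)
  tr <- simulate_acidification(cfg)
  prof <- build_flux_profile(tr$times, tr$pH_i, tr$pH_o, cfg$buffer,
                             cfg$radius)
  fit <- fit_permeability_ghk(prof, cfg$buffer,
                              pH_start = cfg$external$pH_initial)
  expect_equal(fit$P, cfg$P_Hplus, tolerance = 0.05)
  # the recovered effective capacitance is of the configured order
  expect_gt(fit$C_spec_eff, cfg$C_spec / 5)
  expect_lt(fit$C_spec_eff, cfg$C_spec * 5)
})
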