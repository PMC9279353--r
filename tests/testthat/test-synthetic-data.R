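test_that("external pH course is flat, continuous and exponential", {
  crs <- external_course(pH_initial = 7.6, pH_final = 6.9,
                         arrival_time = 60, tau = 120)
  expect_equal(external_ph(0, crs), 7.6)
  expect_equal(external_ph(59.999, crs), 7.6)
  expect_equal(external_ph(60, crs), 7.6, tolerance = 1e-12)  # continuity
  expect_equal(external_ph(180, crs), 6.9 + 0.7 * exp(-1), tolerance = 1e-12)
  expect_equal(external_ph(1e6, crs), 6.9)
  expect_error(external_course(pH_initial = 6, pH_final = 7), "pH_final")
  expect_error(external_course(tau = 0))
})

test_that("an impermeable membrane keeps the lumen at rest", {
  cfg <- short_config(P_Hplus = 0, acid = strong_acid(P_anion = 0))
  tr <- simulate_acidification(cfg)
  expect_equal(tr$pH_i, rep(7.6, nrow(tr)))
  expect_equal(tr$dpsi, rep(0, nrow(tr)))
  expect_equal(tr$J_Hplus, rep(0, nrow(tr)))
})

test_that("clamped strong-acid run follows Fick's law and equilibrates", {
  cfg <- simulation_config(clamp_potential = TRUE, duration = 600,
                           radius = 2e-4, P_Hplus = 3e-2)
  tr <- simulate_acidification(cfg)
  H_i <- 10^(-tr$pH_i) / 1000
  H_o <- 10^(-tr$pH_o) / 1000
  expect_equal(tr$J_Hplus, cfg$P_Hplus * (H_o - H_i), tolerance = 1e-10)
  # small fast vesicle approaches chemical equilibrium with the exterior
  expect_equal(tr$pH_i[nrow(tr)], tr$pH_o[nrow(tr)], tolerance = 0.005)
  expect_equal(tr$dpsi, rep(0, nrow(tr)))
})

test_that("proton bookkeeping ties pH steps to the cumulative influx", {
  tr <- simulate_acidification(short_config())
  buf <- hepes_buffer()
  mid <- (tr$pH_i[-nrow(tr)] + tr$pH_i[-1]) / 2
  lhs <- buffer_capacity(mid, buf) * (-diff(tr$pH_i))
  rhs <- diff(tr$cum_protons)
  keep <- rhs > 1e-15
  expect_lt(max(abs(lhs[keep] / rhs[keep] - 1)), 1e-3)
  # cumulative influx never decreases during acidification
  expect_true(all(diff(tr$cum_protons) > -1e-18))
})

test_that("acidification is monotone while the gradient points inward", {
  tr <- simulate_acidification(short_config())
  expect_true(all(tr$pH_o <= tr$pH_i + 1e-12))
  expect_true(all(diff(tr$pH_i) <= 1e-12))
})

test_that("potential buildup saturates the flux below the Fick prediction", {
  cfg_free <- short_config(acid = strong_acid(P_anion = 0))
  cfg_clamp <- short_config(acid = strong_acid(P_anion = 0),
                            clamp_potential = TRUE)
  free <- simulate_acidification(cfg_free)
  clamp <- simulate_acidification(cfg_clamp)
  # potential rises monotonically while the gradient persists
  post <- free$times > cfg_free$external$arrival_time + 5
  expect_true(all(diff(free$dpsi[post]) > 0))
  # at matched gradient, the unclamped flux lies below the clamped one
  dH_free <- 10^(-free$pH_o) / 1000 - 10^(-free$pH_i) / 1000
  dH_clamp <- 10^(-clamp$pH_o) / 1000 - 10^(-clamp$pH_i) / 1000
  # compare on the rising branch of the clamped gradient, where the
  # gradient-to-flux map is single valued
  rise <- seq_len(which.max(dH_clamp))
  sel <- free$dpsi > 1e-3 & dH_free > min(dH_clamp[rise]) &
    dH_free < max(dH_clamp[rise])
  J_clamp_matched <- approx(dH_clamp[rise], clamp$J_Hplus[rise],
                            xout = dH_free[sel], ties = mean)$y
  expect_true(all(free$J_Hplus[sel] < J_clamp_matched))
  # Fick prediction exceeded nowhere
  expect_true(all(free$J_Hplus[sel] < cfg_free$P_Hplus * dH_free[sel]))
})

test_that("halving the step leaves the endpoint essentially unchanged", {
  cfg1 <- simulation_config(dt = 0.1)
  cfg2 <- simulation_config(dt = 0.05)
  end1 <- tail(simulate_acidification(cfg1)$pH_i, 1)
  end2 <- tail(simulate_acidification(cfg2)$pH_i, 1)
  expect_lt(abs(end1 - end2), 1e-4)
})

test_that("weak-acid runs carry neutral-acid flux and acidify faster", {
  cfg_w <- short_config(P_Hplus = 6.2e-3, acid = formic_acid())
  cfg_s <- short_config(P_Hplus = 6.2e-3, acid = strong_acid())
  w <- simulate_acidification(cfg_w)
  s <- simulate_acidification(cfg_s)
  expect_true(all(s$J_HA == 0))
  expect_gt(max(w$J_HA), 0)
  expect_lt(tail(w$pH_i, 1), tail(s$pH_i, 1))
  # neutral influx carries no charge: potential stays lower than the
  # strong-acid run despite the larger total proton flux
  expect_lt(max(w$dpsi), max(s$dpsi) * 1.05)
})

test_that("configuration guards reject degenerate inputs", {
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(duration = 0.01), "duration")
  expect_error(simulation_config(seed = NULL), "seed")
  expect_error(simulate_cohort(3, simulation_config()), "seed")
})

test_that("cohort radii are reproducible and dispersed", {
  a <- simulate_cohort(4, short_config(duration = 10), seed = 5)
  b <- simulate_cohort(4, short_config(duration = 10), seed = 5)
  ra <- vapply(a, function(tr) attr(tr, "radius"), numeric(1))
  rb <- vapply(b, function(tr) attr(tr, "radius"), numeric(1))
  expect_identical(ra, rb)
  expect_gt(sd(ra) / mean(ra), 0.01)
  expect_equal(vapply(a, function(tr) tr$vesicle_id[1], numeric(1)), 1:4)
})

test_that("calibrated neutral permeability hits the target effective slope", {
  cfg <- simulation_config(P_Hplus = 6.2e-3, acid = formic_acid())
  P_HA <- calibrate_neutral_permeability(4, cfg)
  expect_gt(P_HA, 0)
  # ground-truth check: rerun clamped with the calibrated value and regress
  cfg2 <- simulation_config(P_Hplus = 6.2e-3,
                            acid = formic_acid(P_HA = P_HA),
                            clamp_potential = TRUE)
  tr <- simulate_acidification(cfg2)
  dH <- 10^(-tr$pH_o) / 1000 - 10^(-tr$pH_i) / 1000
  on <- tr$pH_o < 7.58 & dH > 0 & dH <= 0.25 * max(dH[tr$pH_o < 7.58])
  slope <- sum(tr$J_HA[on] * dH[on]) / sum(dH[on]^2)
  expect_equal(slope / cfg$P_Hplus, 4, tolerance = 0.05)
})
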