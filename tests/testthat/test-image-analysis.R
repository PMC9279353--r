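test_that("noiseless rendering is exact and deterministic", {
  fx <- noiseless_fixture()
  st <- fx$stack
  crv <- calibration_curve()
  # lumen disc mean equals the calibrated intensity exactly
  expect_equal(measure_lumen_intensity(st[, , 2, 1], 64, 64, 20),
               ph_to_intensity(fx$trace$pH_i[1], crv))
  # background equals the external calibrated intensity exactly
  det <- data.frame(x = 64, y = 64, radius_px = 20)
  expect_equal(measure_background(st[, , 2, 1], det),
               ph_to_intensity(fx$trace$pH_o[1], crv))
  # last frame reflects the acidified exterior
  f <- dim(st)[4]
  expect_equal(measure_background(st[, , 2, f], det),
               ph_to_intensity(fx$trace$pH_o[f], crv))
})

test_that("rendering with a fixed seed is bit-identical", {
  tr <- simulate_acidification(short_config(duration = 20))
  img <- image_render_config(positions = matrix(c(64, 64), 1, 2), seed = 9)
  a <- render_timelapse(list(tr), calibration_curve(), img)
  b <- render_timelapse(list(tr), calibration_curve(), img)
  expect_identical(as.numeric(a), as.numeric(b))
  img2 <- image_render_config(positions = matrix(c(64, 64), 1, 2), seed = 10)
  c <- render_timelapse(list(tr), calibration_curve(), img2)
  expect_false(identical(as.numeric(a), as.numeric(c)))
})

test_that("rendering rejects discs that exit the frame and missing seeds", {
  tr <- simulate_acidification(short_config(duration = 20))
  img <- image_render_config(positions = matrix(c(10, 10), 1, 2), seed = 1)
  expect_error(render_timelapse(list(tr), calibration_curve(), img),
               "exits the frame")
  expect_error(image_render_config(positions = matrix(c(64, 64), 1, 2)),
               "seed")
})

test_that("render-detect round trip recovers centre and radius", {
  fx <- noiseless_fixture()
  d <- detect_vesicles(fx$stack[, , 1, 1], c(10, 30))
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$x - 64)^2 + (d$y - 64)^2), 1.5)
  expect_lt(abs(d$radius_px - 20), 1.5)
})

test_that("detection separates nearby vesicles and ignores blank frames", {
  tr <- simulate_acidification(short_config(duration = 20))
  img <- image_render_config(positions = matrix(c(60, 120, 60, 60), 2, 2),
                             poisson_scale = 0, read_sd = 0, seed = 2)
  st <- render_timelapse(list(tr, tr), calibration_curve(), img)
  d <- detect_vesicles(st[, , 1, 1], c(10, 30))
  expect_equal(nrow(d), 2)
  expect_equal(nrow(detect_vesicles(matrix(7, 128, 128), c(10, 30))), 0)
  expect_error(detect_vesicles(matrix(0, 64, 64), c(30, 10)), "radius")
  expect_error(detect_vesicles(array(0, c(4, 4, 2)), c(10, 30)), "2-D")
})

test_that("radius estimate bias stays below 5% across the search range", {
  tr <- simulate_acidification(short_config(duration = 10))
  for (r_um in c(6, 8, 10, 12)) {
    attr(tr, "radius") <- r_um * 1e-4
    img <- image_render_config(positions = matrix(c(64, 64), 1, 2),
                               poisson_scale = 0, read_sd = 0, seed = 2)
    st <- render_timelapse(list(tr), calibration_curve(), img)
    d <- detect_vesicles(st[, , 1, 1], c(8, 30))
    expect_equal(nrow(d), 1)
    r_px <- r_um / 0.5
    expect_lt(abs(d$radius_px - r_px) / r_px, 0.05)
  }
})

test_that("greedy tracking keeps stable IDs and gates long jumps", {
  # static detections over 10 frames -> one ID each
  det <- do.call(rbind, lapply(1:10, function(f) {
    data.frame(frame = f, x = c(30, 90), y = c(40, 40), radius_px = 10)
  }))
  tk <- track_vesicles(det, max_displacement = 5)
  expect_equal(length(unique(tk$vesicle_id)), 2)
  expect_equal(as.vector(table(tk$vesicle_id)), c(10L, 10L))
  # order within a frame does not matter
  det_shuffled <- det[order(det$frame, -det$x), ]
  tk2 <- track_vesicles(det_shuffled, max_displacement = 5)
  expect_equal(tk2[order(tk2$vesicle_id, tk2$frame), ],
               tk[order(tk$vesicle_id, tk$frame), ],
               ignore_attr = TRUE)
  # a jump beyond the gate starts a new ID
  det3 <- data.frame(frame = c(1, 2), x = c(30, 60), y = c(40, 40),
                     radius_px = 10)
  tk3 <- track_vesicles(det3, max_displacement = 5)
  expect_equal(length(unique(tk3$vesicle_id)), 2)
  # disappearance beyond the allowed gap also starts a new ID
  det4 <- data.frame(frame = c(1, 5), x = c(30, 30), y = c(40, 40),
                     radius_px = 10)
  tk4 <- track_vesicles(det4, max_displacement = 5, max_gap = 1)
  expect_equal(length(unique(tk4$vesicle_id)), 2)
  # but a single missed frame is bridged
  det5 <- data.frame(frame = c(1, 3), x = c(30, 31), y = c(40, 40),
                     radius_px = 10)
  tk5 <- track_vesicles(det5, max_displacement = 5, max_gap = 1)
  expect_equal(length(unique(tk5$vesicle_id)), 1)
})

test_that("two vesicles that would swap stay on their own tracks", {
  # approaching then receding; nearest-neighbour keeps identity because the
  # true step (2 px) is far below the cross-assignment distance
  xs1 <- c(30, 32, 34, 36, 34, 32, 30)
  xs2 <- c(70, 68, 66, 64, 66, 68, 70)
  det <- do.call(rbind, lapply(seq_along(xs1), function(f) {
    data.frame(frame = f, x = c(xs1[f], xs2[f]), y = 40, radius_px = 8)
  }))
  tk <- track_vesicles(det, max_displacement = 10)
  expect_equal(length(unique(tk$vesicle_id)), 2)
  t1 <- tk[tk$vesicle_id == 1, ]
  expect_equal(t1$x, xs1)
})

test_that("lumen measurement respects the shrink factor", {
  # disc 500 with bright ring 2000 at r = 20
  frame <- matrix(800, 128, 128)
  d2 <- (row(frame) - 65)^2 + (col(frame) - 65)^2
  frame[d2 <= 20^2] <- 500
  frame[d2 > 18^2 & d2 <= 20^2] <- 2000
  expect_equal(measure_lumen_intensity(frame, 64, 64, 20, shrink = 0.7), 500)
  expect_gt(measure_lumen_intensity(frame, 64, 64, 20, shrink = 0.99), 500)
  expect_error(measure_lumen_intensity(frame, 5, 5, 20), "exits the frame")
  expect_error(measure_lumen_intensity(frame, 64, 64, 20, shrink = 1.2))
})

test_that("background excludes dilated vesicle discs", {
  frame <- matrix(800, 128, 128)
  d2 <- (row(frame) - 65)^2 + (col(frame) - 65)^2
  frame[d2 <= 24^2] <- 500
  det <- data.frame(x = 64, y = 64, radius_px = 20)
  expect_equal(measure_background(frame, det, margin = 1.2), 800)
  # no vesicles -> global mean
  expect_equal(measure_background(frame, det[0, , drop = FALSE]), mean(frame))
  big <- data.frame(x = 64, y = 64, radius_px = 1000)
  expect_error(measure_background(frame, big), "no background")
})

test_that("noisy lumen means stay near truth for large discs", {
  tr <- simulate_acidification(short_config(duration = 10))
  img <- image_render_config(positions = matrix(c(64, 64), 1, 2), seed = 6)
  st <- render_timelapse(list(tr), calibration_curve(), img)
  truth <- ph_to_intensity(tr$pH_i[1], calibration_curve())
  got <- measure_lumen_intensity(st[, , 2, 1], 64, 64, 20, shrink = 0.7)
  # > 300 pixels in the disc: mean within 1%
  expect_equal(got, truth, tolerance = 0.01)
})

test_that("TIFF round trip preserves the stack to quantisation accuracy", {
  fx <- noiseless_fixture(duration = 20)
  p1 <- tempfile(fileext = ".tif"); p2 <- tempfile(fileext = ".tif")
  on.exit(unlink(c(p1, p2)), add = TRUE)
  write_stack_tiff(fx$stack, p1, p2)
  back <- read_stack_tiff(p1, p2, pixel_size = 0.5, frame_interval = 5)
  expect_equal(dim(back), dim(fx$stack))
  expect_lt(max(abs(as.numeric(back) - as.numeric(fx$stack))), 0.51)
  expect_equal(attr(back, "pixel_size"), 0.5)
})
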