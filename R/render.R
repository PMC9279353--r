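#' Synthetic image-rendering configuration
#'
#' Geometry, optics-free intensity model and noise model for rendering
#' two-channel confocal-like time-lapse stacks from simulated traces.
#' Coordinates are 0-based pixel indices with vesicle centres at integer
#' positions; radii are converted to pixels through `pixel_size`.
#'
#' @param size Image size in pixels, `c(height, width)`. Default c(256, 256).
#' @param pixel_size Pixel size, um/px (> 0). Default 0.5.
#' @param frame_interval Frame interval, s. Default 5.
#' @param positions n x 2 matrix of vesicle centre positions (x, y) in px.
#' @param drift n x 2 matrix of per-frame centre drift (x, y) in px/frame.
#'   Default no drift.
#' @param lumen_gain Multiplicative gain applied to calibration-curve
#'   intensities in the lumen channel. Default 1.
#' @param membrane_intensity Membrane-ring intensity, arbitrary units.
#' @param membrane_background Membrane-channel background level.
#' @param ring_thickness Membrane ring thickness, px. Default 3.
#' @param poisson_scale Poisson noise scaling: a pixel with mean `I` is drawn
#'   as `poisson_scale * rpois(I / poisson_scale)`. 0 disables shot noise.
#' @param read_sd Gaussian read-noise standard deviation. 0 disables.
#' @param seed Integer seed for the noise draw (required).
#' @return An object of class `image_render_config`.
#' @export
image_render_config <- function(size = c(256L, 256L), pixel_size = 0.5,
                                frame_interval = 5, positions,
                                drift = NULL, lumen_gain = 1,
                                membrane_intensity = 3000,
                                membrane_background = 100,
                                ring_thickness = 3,
                                poisson_scale = 1, read_sd = 5, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("image_render_config: an explicit integer seed is required")
  }
  stopifnot(pixel_size > 0, frame_interval > 0, is.matrix(positions),
            ncol(positions) == 2L, ring_thickness > 0,
            poisson_scale >= 0, read_sd >= 0)
  if (any(positions[, 1] < 0 | positions[, 1] >= size[2] |
            positions[, 2] < 0 | positions[, 2] >= size[1])) {
    stop("image_render_config: vesicle positions must lie inside the frame")
  }
  if (is.null(drift)) drift <- matrix(0, nrow(positions), 2)
  structure(
    list(size = as.integer(size), pixel_size = pixel_size,
         frame_interval = frame_interval, positions = positions,
         drift = drift, lumen_gain = lumen_gain,
         membrane_intensity = membrane_intensity,
         membrane_background = membrane_background,
         ring_thickness = ring_thickness,
         poisson_scale = poisson_scale, read_sd = read_sd,
         seed = as.integer(seed)),
    class = "image_render_config"
  )
}

# squared distance of every pixel to a centre (0-based pixel coordinates)
pixel_dist2 <- function(size, cx, cy) {
  xs <- matrix(rep(0:(size[2] - 1), each = size[1]), nrow = size[1])
  ys <- matrix(rep(0:(size[1] - 1), times = size[2]), nrow = size[1])
  (xs - cx)^2 + (ys - cy)^2
}

#' Render a two-channel synthetic time-lapse stack
#'
#' Channel 1 (membrane dye): an annular ring of the configured thickness at
#' each vesicle's radius over a flat background. Channel 2 (lumenal pH dye):
#' a uniform disc at `ph_to_intensity(pH_i)` for each vesicle over a
#' background at `ph_to_intensity(pH_o)`. Poisson shot noise and Gaussian
#' read noise are applied per pixel with the configured seed; rendering is
#' bit-reproducible for a fixed seed.
#'
#' @param traces List of `guv_trace` objects (one per vesicle), sampled at
#'   the frame interval.
#' @param curve A [calibration_curve()].
#' @param img An [image_render_config()].
#' @return An object of class `guv_stack`: numeric array with dimensions
#'   (height, width, 2 channels, frames), attributes `pixel_size` (um/px)
#'   and `frame_interval` (s).
#' @export
render_timelapse <- function(traces, curve, img) {
  stopifnot(inherits(img, "image_render_config"))
  if (inherits(traces, "guv_trace")) traces <- list(traces)
  n_ves <- length(traces)
  if (nrow(img$positions) != n_ves) {
    stop("render_timelapse: one position per trace is required")
  }
  n_frames <- nrow(traces[[1]])
  for (tr in traces) {
    if (nrow(tr) != n_frames) stop("render_timelapse: traces of unequal length")
    dt <- diff(tr$times)
    if (any(abs(dt - img$frame_interval) > 1e-9)) {
      stop("render_timelapse: traces must be sampled at the frame interval")
    }
  }
  r_px <- vapply(traces, function(tr) attr(tr, "radius") * 1e4 / img$pixel_size,
                 numeric(1))
  half_ring <- img$ring_thickness / 2

  # reject vesicles whose disc (+ ring) ever exits the frame
  for (v in seq_len(n_ves)) {
    cx <- img$positions[v, 1] + img$drift[v, 1] * (0:(n_frames - 1))
    cy <- img$positions[v, 2] + img$drift[v, 2] * (0:(n_frames - 1))
    rmax <- r_px[v] + half_ring
    if (any(cx - rmax < 0 | cx + rmax > img$size[2] - 1 |
              cy - rmax < 0 | cy + rmax > img$size[1] - 1)) {
      stop(sprintf("render_timelapse: vesicle %d exits the frame", v))
    }
  }

  stack <- array(0, dim = c(img$size[1], img$size[2], 2L, n_frames))
  set.seed(img$seed)
  for (f in seq_len(n_frames)) {
    mem <- matrix(img$membrane_background, img$size[1], img$size[2])
    lum <- matrix(img$lumen_gain *
                    ph_to_intensity(traces[[1]]$pH_o[f], curve),
                  img$size[1], img$size[2])
    for (v in seq_len(n_ves)) {
      cx <- img$positions[v, 1] + img$drift[v, 1] * (f - 1)
      cy <- img$positions[v, 2] + img$drift[v, 2] * (f - 1)
      d2 <- pixel_dist2(img$size, cx, cy)
      ring <- abs(sqrt(d2) - r_px[v]) <= half_ring
      mem[ring] <- img$membrane_intensity
      disc <- d2 <= r_px[v]^2
      lum[disc] <- img$lumen_gain * ph_to_intensity(traces[[v]]$pH_i[f], curve)
    }
    for (ch in 1:2) {
      frame <- if (ch == 1) mem else lum
      if (img$poisson_scale > 0) {
        frame <- img$poisson_scale *
          stats::rpois(length(frame), frame / img$poisson_scale)
        dim(frame) <- c(img$size[1], img$size[2])
      }
      if (img$read_sd > 0) {
        frame <- frame + stats::rnorm(length(frame), 0, img$read_sd)
        dim(frame) <- c(img$size[1], img$size[2])
      }
      stack[, , ch, f] <- pmax(frame, 0)
    }
  }
  attr(stack, "pixel_size") <- img$pixel_size
  attr(stack, "frame_interval") <- img$frame_interval
  class(stack) <- "guv_stack"
  stack
}

#' Write / read a two-channel stack as multi-page TIFF
#'
#' Each channel is written to its own multi-page 16-bit TIFF (one page per
#' frame), intensities stored as counts out of 65535. Pixel size and frame
#' interval are not carried by the TIFF and must be supplied on read.
#'
#' @param stack A `guv_stack`.
#' @param path_membrane,path_lumen Output TIFF paths for channels 1 and 2.
#' @return Invisibly, the two paths.
#' @export
write_stack_tiff <- function(stack, path_membrane, path_lumen) {
  stopifnot(inherits(stack, "guv_stack"))
  dm <- dim(stack)
  for (ch in 1:2) {
    pages <- lapply(seq_len(dm[4]), function(f) {
      m <- stack[, , ch, f]
      pmin(pmax(round(m), 0), 65535) / 65535
    })
    tiff::writeTIFF(pages, if (ch == 1) path_membrane else path_lumen,
                    bits.per.sample = 16L)
  }
  invisible(c(path_membrane, path_lumen))
}

#' @rdname write_stack_tiff
#' @param pixel_size,frame_interval Metadata to attach on read.
#' @export
read_stack_tiff <- function(path_membrane, path_lumen, pixel_size,
                            frame_interval) {
  mem <- tiff::readTIFF(path_membrane, all = TRUE)
  lum <- tiff::readTIFF(path_lumen, all = TRUE)
  stopifnot(length(mem) == length(lum))
  h <- nrow(mem[[1]]); w <- ncol(mem[[1]])
  stack <- array(0, dim = c(h, w, 2L, length(mem)))
  for (f in seq_along(mem)) {
    stack[, , 1, f] <- mem[[f]] * 65535
    stack[, , 2, f] <- lum[[f]] * 65535
  }
  attr(stack, "pixel_size") <- pixel_size
  attr(stack, "frame_interval") <- frame_interval
  class(stack) <- "guv_stack"
  stack
}
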