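# shift a matrix by (dy, dx), zero-filling vacated cells
shift_mat <- function(M, dy, dx) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- M[ys - dy, xs - dx]
  out
}

# 3x3 box sum
box3 <- function(M) {
  out <- M
  for (dy in -1:1) for (dx in -1:1) {
    if (dy != 0 || dx != 0) out <- out + shift_mat(M, dy, dx)
  }
  out
}

# Sobel gradients; returns list(gx, gy, mag)
sobel_gradient <- function(M) {
  sx <- shift_mat(M, 0, -1); sx1 <- shift_mat(M, 0, 1)
  gx <- (sx - sx1) * 2 +
    (shift_mat(M, -1, -1) - shift_mat(M, -1, 1)) +
    (shift_mat(M, 1, -1) - shift_mat(M, 1, 1))
  sy <- shift_mat(M, -1, 0); sy1 <- shift_mat(M, 1, 0)
  gy <- (sy - sy1) * 2 +
    (shift_mat(M, -1, -1) - shift_mat(M, 1, -1)) +
    (shift_mat(M, -1, 1) - shift_mat(M, 1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Detect vesicles in a membrane-channel frame by circular Hough transform
#'
#' Edge pixels (Sobel gradient magnitude above `edge_threshold` times the
#' frame maximum) vote along their gradient direction, in both orientations,
#' at every candidate radius. Votes are pooled over a 3x3 neighbourhood;
#' candidate centres are ranked by accumulator score, overlapping candidates
#' are suppressed (centres closer than the smaller radius keep the higher
#' score) and the radius of each kept centre is the vote-weighted mean over
#' a window around its peak-vote radius, rounded to an integer pixel.
#' Deterministic.
#'
#' @param frame 2-D numeric matrix (membrane channel).
#' @param radius_range Search range `c(r_min, r_max)` in px (> 0).
#' @param sensitivity Accumulator threshold as a fraction of the ideal
#'   number of centre votes (~ 4 pi r: both ring edges, both gradient
#'   orientations). Default 0.75.
#' @param edge_threshold Edge gate as a fraction of the maximum gradient
#'   magnitude. Default 0.25.
#' @param radius_step Radius search step in px. Default 1.
#' @param peak_fraction Minimum fraction of a candidate centre's votes that
#'   must fall within +/- 3 px of its peak radius; diffuse accumulations
#'   that are not circle-like are rejected. Default 0.6.
#' @return data.frame with columns `x`, `y` (0-based px), `radius_px`,
#'   `score`; zero rows when nothing is detected.
#' @export
detect_vesicles <- function(frame, radius_range, sensitivity = 0.75,
                            edge_threshold = 0.25, radius_step = 1,
                            peak_fraction = 0.6) {
  if (!is.matrix(frame) || length(dim(frame)) != 2L) {
    stop("detect_vesicles: frame must be a 2-D matrix")
  }
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
        radius_range[1] > radius_range[2]) {
    stop("detect_vesicles: degenerate radius range")
  }
  h <- nrow(frame); w <- ncol(frame)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      radius_px = numeric(0), score = numeric(0))
  g <- sobel_gradient(frame)
  # suppress zero-padding artefacts at the frame border
  g$mag[c(1, h), ] <- 0
  g$mag[, c(1, w)] <- 0
  mmax <- max(g$mag)
  if (mmax == 0) return(empty)
  edge <- which(g$mag > edge_threshold * mmax)
  if (length(edge) == 0) return(empty)

  # 0-based coordinates of edge pixels (row = y, col = x)
  ey <- (edge - 1) %% h
  ex <- (edge - 1) %/% h
  ux <- g$gx[edge] / g$mag[edge]
  uy <- g$gy[edge] / g$mag[edge]

  radii <- seq(radius_range[1], radius_range[2], by = radius_step)
  acc <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    cx <- round(c(ex + r * ux, ex - r * ux))
    cy <- round(c(ey + r * uy, ey - r * uy))
    ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
    idx <- cy[ok] + 1 + cx[ok] * h
    A <- matrix(0, h, w)
    tab <- tabulate(idx, nbins = h * w)
    A[] <- tab
    acc[[k]] <- A
  }
  G <- Reduce(`+`, acc)
  G3 <- box3(G)
  acc3 <- lapply(acc, box3)

  # ideal accumulator response: both ring edges vote twice per pixel
  min_votes <- sensitivity * 4 * pi * radius_range[1]
  cand <- which(G3 >= min_votes)
  if (length(cand) == 0) return(empty)
  cand <- cand[order(G3[cand], decreasing = TRUE)]
  cy_c <- (cand - 1) %% h
  cx_c <- (cand - 1) %/% h

  kept <- empty
  for (i in seq_along(cand)) {
    # radius from the per-radius vote histogram at this centre
    hist_r <- vapply(acc3, function(A) A[cand[i]], numeric(1))
    if (sum(hist_r) == 0) next
    # a genuine circle concentrates its votes around one radius (the ring
    # edges straddle it); diffuse multi-radius accumulations are ghosts
    k_max <- which.max(hist_r)
    win <- abs(radii - radii[k_max]) <= 3
    if (sum(hist_r[win]) < peak_fraction * sum(hist_r)) next
    r_est <- round(sum(radii[win] * hist_r[win]) / sum(hist_r[win]))
    score <- sum(hist_r[win])
    if (score < sensitivity * 4 * pi * r_est) next
    if (nrow(kept) > 0) {
      d <- sqrt((kept$x - cx_c[i])^2 + (kept$y - cy_c[i])^2)
      if (any(d < pmin(kept$radius_px, r_est))) next
    }
    kept <- rbind(kept, data.frame(x = cx_c[i], y = cy_c[i],
                                   radius_px = r_est, score = score))
  }
  rownames(kept) <- NULL
  kept
}

# detections for every frame of the membrane channel of a stack
detect_stack <- function(stack, radius_range, ...) {
  stopifnot(inherits(stack, "guv_stack"))
  n_frames <- dim(stack)[4]
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    d <- detect_vesicles(stack[, , 1, f], radius_range, ...)
    if (nrow(d) > 0) d$frame <- f
    out[[f]] <- d
  }
  do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
}

#' Track vesicles across frames by greedy nearest-neighbour linking
#'
#' Candidate links between active tracks and current-frame detections are
#' sorted by ascending Euclidean centre distance and assigned greedily; links
#' longer than `max_displacement` are rejected and start a new ID. A track
#' may skip up to `max_gap` consecutive frames. IDs are never reused, and the
#' assignment does not depend on the detection ordering within a frame.
#'
#' @param detections data.frame with columns `frame`, `x`, `y`, `radius_px`
#'   (and optionally `score`), ordered or orderable by frame.
#' @param max_displacement Maximum link length in px.
#' @param max_gap Maximum number of missed frames bridged by a link.
#'   Default 1.
#' @return data.frame `vesicle_id`, `frame`, `x`, `y`, `radius_px`.
#' @export
track_vesicles <- function(detections, max_displacement, max_gap = 1) {
  if (nrow(detections) == 0) {
    return(data.frame(vesicle_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), radius_px = numeric(0)))
  }
  stopifnot(all(c("frame", "x", "y", "radius_px") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  tracks <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       last_frame = integer(0))
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- detections[detections$frame == f, , drop = FALSE]
    det <- det[order(det$x, det$y), , drop = FALSE]  # canonical order
    det$assigned <- NA_integer_
    active <- tracks[f - tracks$last_frame <= max_gap + 1, , drop = FALSE]
    if (nrow(active) > 0 && nrow(det) > 0) {
      pairs <- expand.grid(ti = seq_len(nrow(active)), di = seq_len(nrow(det)))
      pairs$d <- sqrt((active$x[pairs$ti] - det$x[pairs$di])^2 +
                        (active$y[pairs$ti] - det$y[pairs$di])^2)
      pairs <- pairs[pairs$d <= max_displacement, , drop = FALSE]
      pairs <- pairs[order(pairs$d, active$id[pairs$ti], pairs$di), ,
                     drop = FALSE]
      used_t <- logical(nrow(active)); used_d <- logical(nrow(det))
      for (k in seq_len(nrow(pairs))) {
        ti <- pairs$ti[k]; di <- pairs$di[k]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        det$assigned[di] <- active$id[ti]
      }
    }
    for (di in seq_len(nrow(det))) {
      if (is.na(det$assigned[di])) {
        det$assigned[di] <- next_id
        next_id <- next_id + 1L
      }
      id <- det$assigned[di]
      hit <- tracks$id == id
      if (any(hit)) {
        tracks$x[hit] <- det$x[di]; tracks$y[hit] <- det$y[di]
        tracks$last_frame[hit] <- f
      } else {
        tracks <- rbind(tracks, data.frame(id = id, x = det$x[di],
                                           y = det$y[di], last_frame = f))
      }
    }
    rows[[fi]] <- data.frame(vesicle_id = det$assigned, frame = f,
                             x = det$x, y = det$y, radius_px = det$radius_px)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$vesicle_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Mean lumenal intensity inside a shrunken disc
#'
#' Averages the lumen-channel pixels within `shrink * radius` of the
#' detection centre; the shrink factor excludes the membrane ring and rim
#' artefacts from the lumen estimate.
#'
#' @param frame 2-D numeric matrix (lumen channel).
#' @param x,y Centre, 0-based px.
#' @param radius_px Detected radius, px.
#' @param shrink Disc shrink fraction in (0, 1). Default 0.7.
#' @return Mean intensity.
#' @export
measure_lumen_intensity <- function(frame, x, y, radius_px, shrink = 0.7) {
  stopifnot(shrink > 0, shrink < 1)
  r <- shrink * radius_px
  if (x - r < 0 || x + r > ncol(frame) - 1 ||
        y - r < 0 || y + r > nrow(frame) - 1) {
    stop("measure_lumen_intensity: measurement disc exits the frame")
  }
  d2 <- pixel_dist2(dim(frame), x, y)
  mean(frame[d2 <= r^2])
}

#' Mean extravesicular background intensity
#'
#' Averages lumen-channel pixels outside every detected vesicle disc dilated
#' by `margin` times its radius.
#'
#' @param frame 2-D numeric matrix (lumen channel).
#' @param detections data.frame with `x`, `y`, `radius_px` (may be empty).
#' @param margin Dilation factor. Default 1.2.
#' @return Mean background intensity.
#' @export
measure_background <- function(frame, detections, margin = 1.2) {
  mask <- matrix(TRUE, nrow(frame), ncol(frame))
  if (nrow(detections) > 0) {
    for (i in seq_len(nrow(detections))) {
      d2 <- pixel_dist2(dim(frame), detections$x[i], detections$y[i])
      mask[d2 <= (margin * detections$radius_px[i])^2] <- FALSE
    }
  }
  if (!any(mask)) stop("measure_background: no background pixels left")
  mean(frame[mask])
}

#' Detect, track and measure a full stack
#'
#' Runs [detect_vesicles()] on every membrane-channel frame, links the
#' detections with [track_vesicles()], and measures per-frame lumenal and
#' background intensity on the lumen channel.
#'
#' @param stack A `guv_stack`.
#' @param radius_range Hough radius search range, px.
#' @param max_displacement Tracking gate, px; must exceed the centre
#'   jitter of the detector (a few px) and stay below half the minimum
#'   vesicle separation. Default 8.
#' @param shrink Lumen measurement disc fraction. Default 0.7.
#' @param margin Background exclusion dilation. Default 1.2.
#' @param ... Further arguments to [detect_vesicles()].
#' @return data.frame with columns `vesicle_id`, `frame`, `t_s`, `x_px`,
#'   `y_px`, `radius_px`, `radius_um`, `lumen_intensity`,
#'   `background_intensity`.
#' @export
measure_stack <- function(stack, radius_range, max_displacement = 8,
                          shrink = 0.7, margin = 1.2, ...) {
  stopifnot(inherits(stack, "guv_stack"))
  det <- detect_stack(stack, radius_range, ...)
  if (is.null(det) || nrow(det) == 0) {
    stop("measure_stack: no vesicles detected")
  }
  tracks <- track_vesicles(det, max_displacement)
  px <- attr(stack, "pixel_size")
  dt <- attr(stack, "frame_interval")
  tracks$t_s <- (tracks$frame - 1) * dt
  tracks$lumen_intensity <- NA_real_
  tracks$background_intensity <- NA_real_
  for (f in unique(tracks$frame)) {
    rows <- which(tracks$frame == f)
    lum <- stack[, , 2, f]
    bg <- measure_background(lum, data.frame(x = tracks$x[rows],
                                             y = tracks$y[rows],
                                             radius_px = tracks$radius_px[rows]),
                             margin)
    for (i in rows) {
      tracks$lumen_intensity[i] <- measure_lumen_intensity(
        lum, tracks$x[i], tracks$y[i], tracks$radius_px[i], shrink)
      tracks$background_intensity[i] <- bg
    }
  }
  data.frame(
    vesicle_id = tracks$vesicle_id, frame = tracks$frame, t_s = tracks$t_s,
    x_px = tracks$x, y_px = tracks$y, radius_px = tracks$radius_px,
    radius_um = tracks$radius_px * px,
    lumen_intensity = tracks$lumen_intensity,
    background_intensity = tracks$background_intensity
  )
}
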