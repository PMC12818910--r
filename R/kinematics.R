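# Tip kinematics: velocity dL/dt from the arc-length cell length L and
# growth direction delta-theta from consecutive tip displacements.
#
# Angle convention: displacements are flipped to mathematical orientation
# (y up) before angles are taken, so positive delta-theta is
# counterclockwise on a screen-up display. The reference axis defaults to
# the bottom-to-tip direction of the reference frame's centerline, making
# delta-theta ~ 0 mean "growing straight along the initial axis".

#' Tip velocity from a length series
#'
#' Forward difference `(L[t] - L[t-1]) / dt`, assigned to frame t; the
#' first frame is NA. Optional centered moving-average smoothing.
#'
#' @param L_series per-frame cell lengths, micrometers.
#' @param dt frame interval in time units.
#' @param window odd moving-average window (1 = off, the default).
#' @return numeric vector of dL/dt, same length as `L_series`.
#' @export
tip_velocity <- function(L_series, dt, window = 1L) {
  if (length(L_series) < 2)
    stop("at least two frames are required to compute a velocity")
  v <- c(NA_real_, diff(L_series) / dt)
  if (window > 1L) {
    if (window %% 2 == 0) stop("window must be odd")
    sm <- stats::filter(v[-1], rep(1 / window, window), sides = 2)
    v <- c(NA_real_, ifelse(is.na(sm), v[-1], as.numeric(sm)))
  }
  v
}

#' Growth direction from tip positions
#'
#' Signed angle (degrees) from `reference_axis` to the tip displacement
#' `tip[t] - tip[t-1]`, positive counterclockwise on screen (image y is
#' flipped before the angle is taken). Zero displacement carries the
#' previous angle forward and sets a flag.
#'
#' @param tips n x 2 matrix of per-frame tip (x, y), px, in the normalized
#'   coordinate system.
#' @param reference_axis c(x, y) direction in image coordinates.
#' @param zero_tol displacement norm (px) below which it counts as zero.
#' @return data.frame with `delta_theta_deg` (frame 0 = NA) and
#'   `zero_disp_flag`.
#' @export
velocity_direction <- function(tips, reference_axis, zero_tol = 1e-9) {
  n <- nrow(tips)
  if (n < 2) stop("at least two frames are required")
  ref <- c(reference_axis[1], -reference_axis[2])  # to math orientation
  nr <- sqrt(sum(ref^2))
  if (nr == 0) stop("reference_axis must be nonzero")
  ref <- ref / nr
  ang <- rep(NA_real_, n)
  flag <- rep(FALSE, n)
  last <- NA_real_
  for (t in 2:n) {
    d <- c(tips[t, 1] - tips[t - 1, 1], -(tips[t, 2] - tips[t - 1, 2]))
    if (sqrt(sum(d^2)) < zero_tol) {
      ang[t] <- last
      flag[t] <- TRUE
      next
    }
    a <- atan2(ref[1] * d[2] - ref[2] * d[1],
               ref[1] * d[1] + ref[2] * d[2]) * 180 / pi
    if (a <= -180) a <- a + 360
    ang[t] <- a
    last <- a
  }
  data.frame(delta_theta_deg = ang, zero_disp_flag = flag)
}

#' Build the tip trace from per-frame centerlines
#'
#' Maps tip/bottom coordinates into the normalized frame (when transforms
#' are supplied), computes L from the centerline arc length, and derives
#' dL/dt and delta-theta.
#'
#' @param centerlines list of oriented `cell_centerline`s, one per frame.
#' @param transforms optional list of `rigid_transform` mapping each frame
#'   into the reference frame (NULL if the centerlines were computed on
#'   already-aligned images).
#' @param dt frame interval; `pixel_size` micrometers per px.
#' @param dim c(rows, cols) of the frames (needed when transforms given).
#' @param reference_axis c(x, y) or NULL for the default (bottom-to-tip of
#'   the first frame's centerline).
#' @param velocity_window moving-average window for dL/dt (1 = off).
#' @return a `tip_trace` data.frame: frame, time, tip_x, tip_y, bottom_x,
#'   bottom_y, L_um, dLdt, delta_theta_deg, zero_disp_flag.
#' @export
build_tip_trace <- function(centerlines, transforms = NULL, dt, pixel_size,
                            dim = NULL, reference_axis = NULL,
                            velocity_window = 1L) {
  nf <- length(centerlines)
  if (!is.null(transforms) && length(transforms) != nf)
    stop("frame-count mismatch between centerlines and transforms")
  tips <- t(vapply(centerlines, function(cl) cl$tip_point, numeric(2)))
  bots <- t(vapply(centerlines, function(cl) cl$bottom_point, numeric(2)))
  if (!is.null(transforms)) {
    if (is.null(dim)) stop("dim is required when transforms are supplied")
    for (i in seq_len(nf)) {
      tips[i, ] <- transform_points(tips[i, , drop = FALSE], transforms[[i]],
                                    dim)
      bots[i, ] <- transform_points(bots[i, , drop = FALSE], transforms[[i]],
                                    dim)
    }
  }
  L <- vapply(centerlines, function(cl) max(cl$s_um), 1)
  if (any(L <= 0)) stop("non-positive cell length")
  if (is.null(reference_axis)) reference_axis <- tips[1, ] - bots[1, ]
  dLdt <- tip_velocity(L, dt, velocity_window)
  dird <- velocity_direction(tips, reference_axis)
  frames <- vapply(centerlines, function(cl) cl$frame_index, 1L)
  structure(data.frame(frame = frames, time = frames * dt,
                       tip_x = tips[, 1], tip_y = tips[, 2],
                       bottom_x = bots[, 1], bottom_y = bots[, 2],
                       L_um = L, dLdt = dLdt,
                       delta_theta_deg = dird$delta_theta_deg,
                       zero_disp_flag = dird$zero_disp_flag),
            class = c("tip_trace", "data.frame"))
}

#' Plot a tip trace (velocity and direction vs time)
#' @param trace a `tip_trace`.
#' @param path PNG output path.
#' @param time_unit axis label for time.
#' @return `path`, invisibly.
#' @export
plot_tip_trace <- function(trace, path, time_unit = "min") {
  png(path, width = 900, height = 400)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  # restore par while the png device is still current, then close it
  on.exit({ graphics::par(old); dev.off() })
  plot(trace$time, trace$dLdt, type = "b", pch = 16,
       xlab = paste0("time (", time_unit, ")"),
       ylab = paste0("dL/dt (um/", time_unit, ")"), main = "tip velocity")
  abline(h = 0, lty = 3)
  plot(trace$time, trace$delta_theta_deg, type = "b", pch = 16,
       xlab = paste0("time (", time_unit, ")"),
       ylab = "delta theta (deg)", main = "growth direction")
  abline(h = 0, lty = 3)
  invisible(path)
}
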