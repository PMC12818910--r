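# Intracellular signal quantification in the cell coordinate system:
# arc-length intensity profiles along the centerline, kymographs across
# time, and truncated-Gaussian band fitting (nucleus or microtubule band).
#
# "Truncated" means the least-squares fit of baseline + Gaussian is
# restricted to a window of the profile; it is not a renormalized
# truncated-density likelihood -- the data are fluorescence intensities,
# not probabilities. Band "upper and lower ends" default to mu +/- sigma,
# with the multiplier exposed.

#' Intensity profile along a centerline
#'
#' At each arc-length position s the image is sampled along the local
#' normal over `[-halfwidth, +halfwidth]` (bilinear interpolation), and the
#' cross-sectional mean (or max) is recorded. Samples outside the contour,
#' or outside the frame, are excluded.
#'
#' @param frame numeric intensity matrix.
#' @param centerline oriented `cell_centerline`.
#' @param halfwidth cross-sectional half-width in micrometers, or NULL for
#'   the default 40% of the local cell width (requires `contour`).
#' @param step arc-length sampling step, micrometers.
#' @param contour optional [cell_contour()] used to clip samples.
#' @param stat `"mean"` (default) or `"max"` across the cross-section.
#' @return an `axial_profile`: `s_um`, `intensity`, `frame_index`,
#'   `L_um`, `sampling_halfwidth`.
#' @export
profile_along_centerline <- function(frame, centerline, halfwidth = NULL,
                                     step = 0.5, contour = NULL,
                                     stat = c("mean", "max")) {
  stat <- match.arg(stat)
  px <- centerline$pixel_size
  L <- max(centerline$s_um)
  if (L < 2 * step) stop("centerline shorter than 2 * step")
  s_grid <- seq(0, L, by = step)
  pts <- resample_at(centerline$points, s_grid / px)
  # local tangent by central differences
  tx <- c(pts[2, 1] - pts[1, 1], pts[-1, 1] - pts[-nrow(pts), 1])
  ty <- c(pts[2, 2] - pts[1, 2], pts[-1, 2] - pts[-nrow(pts), 2])
  tn <- sqrt(tx^2 + ty^2); tn[tn == 0] <- 1
  nxv <- -ty / tn; nyv <- tx / tn  # unit normal

  if (is.null(halfwidth)) {
    if (is.null(contour))
      stop("halfwidth = NULL requires a contour to estimate local width")
    cp <- contour$points
    dw <- cpp_dist_to_polyline(pts[, 1], pts[, 2],
                               c(cp[, 1], cp[1, 1]), c(cp[, 2], cp[1, 2]))[, 1]
    hw_px <- 0.4 * dw  # 40% of local half-width * 2 / 2 = 0.4 * radius * 2
  } else {
    hw_px <- rep(halfwidth / px, length(s_grid))
  }
  n_off <- max(3L, ceiling(2 * max(hw_px) / 0.5))
  off <- seq(-1, 1, length.out = n_off)
  intensity <- vapply(seq_along(s_grid), function(i) {
    xs <- pts[i, 1] + off * hw_px[i] * nxv[i]
    ys <- pts[i, 2] + off * hw_px[i] * nyv[i]
    vals <- cpp_bilinear(frame, xs, ys, NA_real_)
    if (!is.null(contour)) {
      inside <- cpp_point_in_polygon(xs, ys, contour$points[, 1],
                                     contour$points[, 2])
      vals[!inside] <- NA_real_
    }
    if (all(is.na(vals))) return(NA_real_)
    if (stat == "mean") mean(vals, na.rm = TRUE) else max(vals, na.rm = TRUE)
  }, 1)
  structure(list(s_um = s_grid, intensity = intensity,
                 frame_index = centerline$frame_index, L_um = L,
                 sampling_halfwidth = if (is.null(halfwidth)) NA_real_
                                      else halfwidth,
                 step = step),
            class = "axial_profile")
}

#' Kymograph from per-frame profiles
#'
#' Places per-frame axial profiles on a common arc-length grid anchored at
#' the bottom (s measured from the bottom) or the tip (s measured back from
#' the tip). Grid extent is the maximum L over frames; bins beyond a
#' frame's L are NA, never 0.
#'
#' @param profiles list of `axial_profile`, one per frame.
#' @param anchor `"bottom"` or `"tip"`.
#' @param dt frame interval for the time axis.
#' @return a `kymograph`: `matrix` (bins x frames), `s_axis`, `t_axis`,
#'   `anchor`.
#' @export
build_kymograph <- function(profiles, anchor = c("bottom", "tip"), dt = 1) {
  anchor <- match.arg(anchor)
  steps <- unique(vapply(profiles, function(p) p$step, 1))
  if (length(steps) != 1) stop("inconsistent profile step across frames")
  Lmax <- max(vapply(profiles, function(p) p$L_um, 1))
  s_axis <- seq(0, Lmax, by = steps)
  mat <- matrix(NA_real_, nrow = length(s_axis), ncol = length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    s <- if (anchor == "bottom") p$s_um else p$L_um - p$s_um
    ok <- s_axis <= p$L_um + steps / 2
    mat[ok, j] <- approx(s, p$intensity, xout = s_axis[ok], rule = 1)$y
  }
  structure(list(matrix = mat, s_axis = s_axis,
                 t_axis = (vapply(profiles, function(p) p$frame_index, 1L)) * dt,
                 anchor = anchor),
            class = "kymograph")
}

gaussian_model <- function(par, s) par[4] + par[1] * exp(-(s - par[2])^2 /
                                                           (2 * par[3]^2))

#' Fit a truncated Gaussian to an axial profile
#'
#' Nonlinear least squares of `B + A exp(-(s - mu)^2 / (2 sigma^2))`
#' restricted to a window. The auto window is `argmax +/- 3 sigma0` clipped
#' to `[0, L]`, with `sigma0` estimated from the full width at half
#' maximum. Band ends are `mu +/- end_k * sigma`.
#'
#' @param profile an `axial_profile`, or a list with `s_um` and `intensity`.
#' @param window c(s_lo, s_hi) in micrometers, or NULL for auto.
#' @param end_k band-end multiplier (default 1: ends at mu +/- sigma).
#' @return a `band_fit`: `A`, `mu`, `sigma`, `B`, `window`, `rms`,
#'   `lower`, `upper`, `n_points`.
#' @export
fit_truncated_gaussian <- function(profile, window = NULL, end_k = 1) {
  s <- profile$s_um
  y <- profile$intensity
  ok <- is.finite(y)
  s <- s[ok]; y <- y[ok]
  if (length(s) < 8) stop("no band detected: too few finite samples")
  if (diff(range(y)) <= 1e-12 * max(abs(y), 1))
    stop("no band detected: flat profile")
  imax <- which.max(y)
  half <- min(y) + (y[imax] - min(y)) / 2
  above <- which(y >= half)
  fwhm <- max(diff(range(s[above])), 2 * mean(diff(s)))
  sigma0 <- (fwhm / 2) / sqrt(2 * log(2))
  if (is.null(window))
    window <- c(max(min(s), s[imax] - 3 * sigma0),
                min(max(s), s[imax] + 3 * sigma0))
  inw <- s >= window[1] & s <= window[2]
  if (sum(inw) < 8) stop("no band detected: window contains < 8 samples")
  sw <- s[inw]; yw <- y[inw]
  span <- diff(range(sw))
  iw <- which.max(yw)
  p0 <- c(A = max(yw) - min(yw), mu = sw[iw], sigma = min(sigma0, span / 2),
          B = min(yw))
  sse <- function(par) sum((yw - gaussian_model(par, sw))^2)
  dx <- mean(diff(sw))
  fit <- optim(p0, sse, method = "L-BFGS-B",
               lower = c(1e-9, window[1], dx / 4, -Inf),
               upper = c(Inf, window[2], 2 * span, Inf),
               control = list(maxit = 500, factr = 1e4))
  if (fit$convergence != 0 && fit$convergence != 52)
    stop("no band detected: fit did not converge")
  par <- fit$par
  if (par[3] > span) stop("no band detected: fitted sigma exceeds window")
  structure(list(A = unname(par[1]), mu = unname(par[2]),
                 sigma = unname(par[3]), B = unname(par[4]),
                 window = window,
                 rms = sqrt(fit$value / sum(inw)),
                 lower = unname(par[2] - end_k * par[3]),
                 upper = unname(par[2] + end_k * par[3]),
                 n_points = sum(inw)),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit> mu = %.3f um, sigma = %.3f um (ends %.3f..%.3f), A = %.1f, B = %.1f, rms = %.2f\n",
              x$mu, x$sigma, x$lower, x$upper, x$A, x$B, x$rms))
  invisible(x)
}

#' Track a band across frames
#'
#' Fits every frame's profile; the window for frame t is auto-initialized
#' from frame t-1's fit (`mu +/- 4 sigma`) when available. Frames whose fit
#' fails are reported as NA rows and do not affect their neighbors.
#'
#' @param profiles list of `axial_profile`, one per frame.
#' @param dt frame interval for the time column.
#' @param end_k band-end multiplier.
#' @return data.frame: frame, time, mu_um, sigma_um, lower_um, upper_um,
#'   A, B, rms, L_um.
#' @export
track_band <- function(profiles, dt = 1, end_k = 1) {
  prev <- NULL
  rows <- lapply(profiles, function(p) {
    win <- if (!is.null(prev))
      c(max(0, prev$mu - 4 * prev$sigma),
        min(p$L_um, prev$mu + 4 * prev$sigma)) else NULL
    fit <- tryCatch(fit_truncated_gaussian(p, win, end_k),
                    error = function(e) NULL)
    if (is.null(fit) && !is.null(win))  # retry with auto window
      fit <- tryCatch(fit_truncated_gaussian(p, NULL, end_k),
                      error = function(e) NULL)
    prev <<- if (is.null(fit)) prev else fit
    if (is.null(fit))
      data.frame(frame = p$frame_index, time = p$frame_index * dt,
                 mu_um = NA_real_, sigma_um = NA_real_, lower_um = NA_real_,
                 upper_um = NA_real_, A = NA_real_, B = NA_real_,
                 rms = NA_real_, L_um = p$L_um)
    else
      data.frame(frame = p$frame_index, time = p$frame_index * dt,
                 mu_um = fit$mu, sigma_um = fit$sigma, lower_um = fit$lower,
                 upper_um = fit$upper, A = fit$A, B = fit$B, rms = fit$rms,
                 L_um = p$L_um)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$mu_um))) stop("band tracking failed on every frame")
  out
}

#' Write a kymograph to 32-bit TIFF and CSV
#'
#' Missing bins are NaN in the TIFF and empty fields in the CSV, never 0.
#'
#' @param kymo a `kymograph`.
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
write_kymograph <- function(kymo, dir) {
  p1 <- file.path(dir, "kymograph.tif")
  write_tiff(kymo$matrix, p1, bits = 32L)
  df <- data.frame(s_bin = rep(seq_along(kymo$s_axis) - 1L,
                               times = ncol(kymo$matrix)),
                   s_um = rep(kymo$s_axis, times = ncol(kymo$matrix)),
                   frame = rep(seq_len(ncol(kymo$matrix)) - 1L,
                               each = nrow(kymo$matrix)),
                   intensity = as.vector(kymo$matrix))
  p2 <- file.path(dir, "kymograph.csv")
  write.csv(df, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
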