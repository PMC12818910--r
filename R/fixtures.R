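# Synthetic tip-growing-cell movies with exact ground truth.
#
# A cell is rendered as a capsule: a tube of constant width around an axis
# polyline, capped by semicircles at both ends. The axis grows from a fixed
# bottom at `growth_rate` per time unit; its growth direction may rotate by
# `bend_rate` degrees per frame. Rendering is analytic -- pixel intensity is
# a linear ramp of the signed distance to the axis across a one-pixel band
# at the capsule boundary -- so contours are subpixel-consistent and free of
# rasterization asymmetry. Per-frame rigid jitter (about the frame center,
# the same convention as the registration module) and additive Gaussian
# noise emulate stage drift and camera noise.

#' Specification of a synthetic growing-cell movie
#'
#' Defaults describe a root-hair-like cell: 0.2 um/px pixels, 10-min frame
#' interval, 3-um tube width, 16-um initial length, growth at 0.2 um/min
#' (the fast end of root-hair growth), moderate stage jitter and camera
#' noise.
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_shape c(rows, cols) in pixels.
#' @param pixel_size micrometers per pixel.
#' @param dt frame interval in time units (minutes by convention).
#' @param width tube width (diameter), micrometers.
#' @param initial_length total cell length bottom-to-tip including both
#'   caps, micrometers; must exceed `width`.
#' @param growth_rate elongation rate, micrometers per time unit; either a
#'   scalar or one value per frame transition (length `n_frames - 1`).
#' @param bend_rate rotation of the growth direction, degrees per frame
#'   (positive bends the tip trajectory counterclockwise on screen).
#' @param jitter_translation_sd per-frame rigid jitter SD, pixels.
#' @param jitter_rotation_sd per-frame rigid jitter SD, degrees.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param band_center_rel band (nucleus stand-in) center as a fraction of
#'   the current length L in `[0, 1]`, or `NULL` for no signal channel.
#' @param band_offset_from_tip if set, overrides `band_center_rel`: the band
#'   center sits at `L - band_offset_from_tip` micrometers (tip-fixed band).
#' @param band_sigma band width parameter sigma, micrometers.
#' @param band_amplitude,band_baseline signal-channel intensities.
#' @param fg,bg contour-channel foreground/background intensities.
#' @param base_cap `"round"` (default) or `"flat"` bottom end.
#' @param seed integer RNG seed for jitter and noise.
#' @return a `synthetic_cell_spec` list.
#' @export
synthetic_cell_spec <- function(n_frames = 8L, frame_shape = c(220L, 160L),
                                pixel_size = 0.2, dt = 10, width = 3,
                                initial_length = 12, growth_rate = 0.2,
                                bend_rate = 0, jitter_translation_sd = 2,
                                jitter_rotation_sd = 1.5, noise_sd = 5,
                                band_center_rel = NULL,
                                band_offset_from_tip = NULL,
                                band_sigma = 2, band_amplitude = 150,
                                band_baseline = 20, fg = 200, bg = 10,
                                base_cap = c("round", "flat"), seed = 1L) {
  base_cap <- match.arg(base_cap)
  spec <- list(n_frames = as.integer(n_frames), frame_shape = frame_shape,
               pixel_size = pixel_size, dt = dt, width = width,
               initial_length = initial_length, growth_rate = growth_rate,
               bend_rate = bend_rate,
               jitter_translation_sd = jitter_translation_sd,
               jitter_rotation_sd = jitter_rotation_sd, noise_sd = noise_sd,
               band_center_rel = band_center_rel,
               band_offset_from_tip = band_offset_from_tip,
               band_sigma = band_sigma, band_amplitude = band_amplitude,
               band_baseline = band_baseline, fg = fg, bg = bg,
               base_cap = base_cap, seed = as.integer(seed))
  if (spec$width <= 0) stop("width must be > 0")
  if (spec$initial_length <= spec$width)
    stop("initial_length must exceed width (capsule must be elongated)")
  if (spec$n_frames < 2) stop("n_frames must be >= 2")
  if (!(length(growth_rate) %in% c(1L, spec$n_frames - 1L)))
    stop("growth_rate must be scalar or length n_frames - 1")
  class(spec) <- "synthetic_cell_spec"
  spec
}

# Axis polyline (pixel coords) for frame t: starts at `base`, initial
# direction `dir0_deg`, each frame's new segment rotated by bend_rate.
# Returns points at <= 1 px spacing.
build_axis <- function(spec, t, base, dir0_deg) {
  px <- spec$pixel_size
  w_px <- spec$width / px
  gr <- if (length(spec$growth_rate) == 1)
    rep(spec$growth_rate, spec$n_frames - 1) else spec$growth_rate
  # axis length excludes the two half-width caps
  len0 <- spec$initial_length / px - w_px
  seg_len <- c(len0, gr * spec$dt / px)  # px added per frame
  pts <- matrix(base, ncol = 2)
  pos <- base
  for (k in seq_len(t + 1)) {
    L <- seg_len[k]
    if (L <= 0) next
    ang <- (dir0_deg + spec$bend_rate * (k - 1)) * pi / 180
    dirv <- c(sin(ang), -cos(ang))  # 0 deg points "up" (decreasing row)
    n_sub <- max(2L, ceiling(L))
    ss <- seq(0, L, length.out = n_sub)[-1]
    pts <- rbind(pts, cbind(pos[1] + ss * dirv[1], pos[2] + ss * dirv[2]))
    pos <- pos + L * dirv
  }
  pts
}

render_capsule <- function(axis, w_px, shape, fg, bg) {
  nr <- shape[1]; nc <- shape[2]
  gx <- rep(0:(nc - 1), each = nr)
  gy <- rep(0:(nr - 1), times = nc)
  ds <- cpp_dist_to_polyline(gx, gy, axis[, 1], axis[, 2])
  cover <- pmin(pmax(0.5 + (w_px / 2 - ds[, 1]), 0), 1)
  list(img = matrix(bg + (fg - bg) * cover, nrow = nr, ncol = nc),
       cover = cover, s_axis = ds[, 2], dist = ds[, 1])
}

#' Generate a synthetic growing-cell movie with ground truth
#'
#' Renders each frame analytically (see the module header), applies seeded
#' per-frame rigid jitter and Gaussian noise, and optionally renders a
#' Gaussian intensity band along the cell axis in a second channel
#' (`"signal"`). Frame 0 carries no jitter and serves as the natural
#' reference for registration.
#'
#' @param spec a [synthetic_cell_spec()].
#' @return list with `seq` (an [image_sequence()], channels `"main"` and
#'   optionally `"signal"`) and `truth`, a list holding `table` (per frame:
#'   0-based index, post-jitter tip/bottom pixel coordinates, length `L_um`,
#'   applied jitter `u`, `v`, `theta_deg`, band center `band_mu_um`) and
#'   `centerlines` (pre-jitter bottom-to-tip polylines, px).
#' @export
make_growing_cell <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  set.seed(spec$seed)
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  px <- spec$pixel_size
  w_px <- spec$width / px
  ctr <- c((nc - 1) / 2, (nr - 1) / 2)
  # bottom anchored low in the frame, growing upward
  base <- c(ctr[1], (nr - 1) * 0.82)
  has_band <- !is.null(spec$band_center_rel) ||
    !is.null(spec$band_offset_from_tip)

  # draw all jitter up front so geometry is independent of band options
  jit <- cbind(u = c(0, rnorm(spec$n_frames - 1, 0, spec$jitter_translation_sd)),
               v = c(0, rnorm(spec$n_frames - 1, 0, spec$jitter_translation_sd)),
               theta = c(0, rnorm(spec$n_frames - 1, 0, spec$jitter_rotation_sd)))

  main <- vector("list", spec$n_frames)
  signal <- if (has_band) vector("list", spec$n_frames) else NULL
  tab <- data.frame(frame = 0:(spec$n_frames - 1), tip_x = NA_real_,
                    tip_y = NA_real_, bottom_x = NA_real_,
                    bottom_y = NA_real_, L_um = NA_real_, u = jit[, "u"],
                    v = jit[, "v"], theta_deg = jit[, "theta"],
                    band_mu_um = NA_real_)
  centerlines <- vector("list", spec$n_frames)

  for (t in 0:(spec$n_frames - 1)) {
    axis <- build_axis(spec, t, base, dir0_deg = 0)
    d0 <- axis[2, ] - axis[1, ]; d0 <- d0 / sqrt(sum(d0^2))
    n_ax <- nrow(axis)
    d1 <- axis[n_ax, ] - axis[n_ax - 1, ]; d1 <- d1 / sqrt(sum(d1^2))
    tip <- axis[n_ax, ] + (w_px / 2) * d1
    bottom <- if (spec$base_cap == "round") axis[1, ] - (w_px / 2) * d0
              else axis[1, ]
    ext <- rbind(bottom, axis, tip)
    # capsule extent: axis polyline dilated by the half-width (the caps
    # reach exactly w/2 beyond the axis ends)
    lims <- c(min(axis[, 1]) - w_px / 2, max(axis[, 1]) + w_px / 2,
              min(axis[, 2]) - w_px / 2, max(axis[, 2]) + w_px / 2)
    if (lims[1] < 1 || lims[3] < 1 || lims[2] > nc - 2 || lims[4] > nr - 2)
      stop("capsule exceeds frame bounds at frame ", t)
    ren <- render_capsule(axis, w_px, spec$frame_shape, spec$fg, spec$bg)
    img <- ren$img
    L_um <- (arc_length(ext)[nrow(ext)]) * px
    cl <- rbind(bottom, axis, tip)

    if (has_band) {
      # arc-length of each pixel along the full centerline (cap offset)
      s_full <- (ren$s_axis + if (spec$base_cap == "round") w_px / 2 else 0) * px
      mu <- if (!is.null(spec$band_offset_from_tip))
        L_um - spec$band_offset_from_tip
      else spec$band_center_rel * L_um
      bandv <- spec$band_baseline +
        spec$band_amplitude * exp(-(s_full - mu)^2 / (2 * spec$band_sigma^2))
      sig <- matrix(spec$bg + (bandv - spec$bg) * ren$cover, nrow = nr)
      tab$band_mu_um[t + 1] <- mu
    }

    th <- jit[t + 1, "theta"] * pi / 180
    if (any(jit[t + 1, ] != 0)) {
      img <- cpp_rigid_transform(img, jit[t + 1, "u"], jit[t + 1, "v"], th,
                                 ctr[1], ctr[2])
      if (has_band)
        sig <- cpp_rigid_transform(sig, jit[t + 1, "u"], jit[t + 1, "v"], th,
                                   ctr[1], ctr[2])
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nrow = nr)
      img[img < 0] <- 0
      if (has_band) {
        sig <- sig + matrix(rnorm(nr * nc, 0, spec$noise_sd), nrow = nr)
        sig[sig < 0] <- 0
      }
    }
    tp <- rotate_points(rbind(tip, bottom), jit[t + 1, "theta"], ctr)
    tp[, 1] <- tp[, 1] + jit[t + 1, "u"]
    tp[, 2] <- tp[, 2] + jit[t + 1, "v"]
    tab$tip_x[t + 1] <- tp[1, 1]; tab$tip_y[t + 1] <- tp[1, 2]
    tab$bottom_x[t + 1] <- tp[2, 1]; tab$bottom_y[t + 1] <- tp[2, 2]
    tab$L_um[t + 1] <- L_um
    centerlines[[t + 1]] <- cl
    main[[t + 1]] <- img
    if (has_band) signal[[t + 1]] <- sig
  }

  channels <- list(main = main)
  if (has_band) channels$signal <- signal
  list(seq = image_sequence(channels, spec$pixel_size, spec$dt),
       truth = list(table = tab, centerlines = centerlines, spec = spec))
}

#' Synthetic 1-D Gaussian band profile
#'
#' Test input for the band-fitting module:
#' `baseline + amplitude * exp(-(s - center)^2 / (2 sigma^2)) + noise`.
#'
#' @param length_px number of samples.
#' @param center,sigma band center and width, in sample units.
#' @param amplitude,baseline intensities.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return numeric vector of length `length_px`; positions are `0:(length_px-1)`.
#' @export
make_band_profile <- function(length_px, center, sigma, amplitude = 100,
                              baseline = 10, noise_sd = 0, seed = 1L) {
  stopifnot(center >= 0, center < length_px, sigma > 0)
  s <- 0:(length_px - 1)
  prof <- baseline + amplitude * exp(-(s - center)^2 / (2 * sigma^2))
  if (noise_sd > 0) {
    set.seed(seed)
    prof <- prof + rnorm(length_px, 0, noise_sd)
  }
  prof
}

#' Write a synthetic movie and its ground truth to disk
#'
#' One multi-page TIFF per channel plus a ground-truth CSV
#' (frame, tip_x, tip_y, bottom_x, bottom_y, L, u, v, theta).
#'
#' @param movie result of [make_growing_cell()].
#' @param dir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
write_movie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  for (ch in names(movie$seq$channels)) {
    p <- file.path(dir, paste0(ch, ".tif"))
    write_tiff(movie$seq$channels[[ch]], p, bits = 32L)
    out[ch] <- p
  }
  gt <- file.path(dir, "ground_truth.csv")
  write.csv(movie$truth$table, gt, row.names = FALSE)
  out["ground_truth"] <- gt
  invisible(out)
}
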