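# Shared fixture builders and small geometric oracles.

# Analytic capsule contour: tube of width w around the segment (x0,y0)-(x1,y1),
# semicircular caps, sampled at ~1 px spacing. Independent of the package's
# contour extraction.
capsule_contour <- function(x0, y0, x1, y1, w, frame_index = 0L) {
  r <- w / 2
  dv <- c(x1 - x0, y1 - y0)
  len <- sqrt(sum(dv^2))
  dv <- dv / len
  nv <- c(-dv[2], dv[1])
  ang0 <- atan2(nv[2], nv[1])
  n_cap <- max(8, ceiling(pi * r))
  cap1 <- t(vapply(seq(0, pi, length.out = n_cap), function(a)
    c(x1, y1) + r * c(cos(ang0 - a), sin(ang0 - a)), numeric(2)))
  cap0 <- t(vapply(seq(0, pi, length.out = n_cap), function(a)
    c(x0, y0) + r * c(cos(ang0 + pi - a), sin(ang0 + pi - a)), numeric(2)))
  n_side <- max(2, ceiling(len))
  ss <- seq(0, 1, length.out = n_side)
  side1 <- cbind(x0 + ss * (x1 - x0) + r * nv[1],
                 y0 + ss * (y1 - y0) + r * nv[2])
  side2 <- cbind(x1 - ss * (x1 - x0) - r * nv[1],
                 y1 - ss * (y1 - y0) - r * nv[2])
  pts <- rbind(side1, cap1[-1, ], side2[-1, ], cap0[-c(1, n_cap), ])
  cell_contour(tipgrow:::resample_closed(pts, 1), frame_index)
}

# Discrete curvature at each vertex of a closed polygon: inverse
# circumradius of consecutive vertex triples.
discrete_curvature <- function(pts) {
  n <- nrow(pts)
  prv <- pts[c(n, 1:(n - 1)), ]
  nxt <- pts[c(2:n, 1), ]
  a <- sqrt(rowSums((pts - prv)^2))
  b <- sqrt(rowSums((nxt - pts)^2))
  cc <- sqrt(rowSums((nxt - prv)^2))
  area2 <- abs((pts[, 1] - prv[, 1]) * (nxt[, 2] - prv[, 2]) -
               (nxt[, 1] - prv[, 1]) * (pts[, 2] - prv[, 2]))
  4 * (area2 / 2) / (a * b * cc + 1e-12)
}

# Small, fast default movie for pipeline-level tests.
small_spec <- function(...) {
  args <- list(n_frames = 4, frame_shape = c(150, 110), initial_length = 10,
               growth_rate = 0.15, jitter_translation_sd = 0,
               jitter_rotation_sd = 0, noise_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_cell_spec, args)
}

# Parameter draws for the acceptance capsule family (widths 10-40 px,
# lengths 60-300 px, bends up to 30 degrees over the movie).
capsule_family <- function(n = 20, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    w <- runif(1, 10, 40)
    list(w_px = w, len_px = runif(1, max(60, w * 2.2), 300),
         bend = runif(1, 0, 30 / 8), seed = i)
  })
}

family_movie <- function(p, n_frames = 3, px = 0.2, ...) {
  shape <- c(max(220, ceiling(p$len_px * 1.6)),
             max(220, ceiling(p$len_px * 1.2)))
  make_growing_cell(synthetic_cell_spec(
    n_frames = n_frames, frame_shape = shape, width = p$w_px * px,
    initial_length = p$len_px * px, growth_rate = 0.1, bend_rate = p$bend,
    jitter_translation_sd = 0, jitter_rotation_sd = 0, noise_sd = 0,
    seed = p$seed, ...))
}

# Full centerline pipeline on one frame of a movie, oriented by the true
# bottom.
centerline_of_frame <- function(mv, f, px = 0.2, k = 5) {
  m <- binarize_otsu(get_frame(mv$seq, f), frame_index = f)
  cc <- extract_contour(m)
  cl <- extrapolate_to_edge(prune_to_centerline(voronoi_skeleton(cc)), cc,
                            k, px)
  tt <- mv$truth$table[f + 1, ]
  orient_centerline(cl, anchor = c(tt$bottom_x, tt$bottom_y))
}
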