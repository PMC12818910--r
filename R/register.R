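# Coordinate normalization: rigid alignment of each frame to a reference
# by maximizing the normalized correlation
#
#   gamma(u, v, theta) = sum (f_ref - mean(f_ref)) (f_t - mean(f_t)) /
#                        sqrt( sum (f_ref - mean(f_ref))^2 *
#                              sum (f_t   - mean(f_t))^2 )
#
# where f_t is the moving frame rotated by theta about the frame center and
# translated by (u, v); pixels mapped from outside the image are 0, and the
# means are spatial means over the full frame. The optimum is found by an
# exhaustive integer grid search followed by half-step bisection refinement.

rigid_identity <- function(frame_index = 0L)
  structure(list(u = 0, v = 0, theta = 0, gamma = 1,
                 frame_index = as.integer(frame_index)),
            class = "rigid_transform")

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> frame %d: u = %.3f px, v = %.3f px, theta = %.3f deg (gamma = %.4f)\n",
              x$frame_index, x$u, x$v, x$theta, x$gamma))
  invisible(x)
}

#' Apply a rigid transform to an image
#'
#' Rotates by `theta` degrees about the frame center, then translates by
#' (`u`, `v`) pixels; bilinear interpolation, zero outside the frame.
#'
#' @param img numeric matrix.
#' @param u,v translation in px (x, y).
#' @param theta rotation in degrees.
#' @return transformed matrix.
#' @export
apply_rigid <- function(img, u, v, theta) {
  ctr <- frame_center(img)
  cpp_rigid_transform(img, u, v, theta * pi / 180, ctr[1], ctr[2])
}

frame_center <- function(img) c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)

# Block-average downsampling by an integer factor (trailing rows/cols that
# do not fill a block are dropped).
downsample <- function(img, f) {
  if (f <= 1) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- rowsum(img, rep(seq_len(nr / f), each = f)) / f
  t(rowsum(t(a), rep(seq_len(nc / f), each = f)) / f)
}

#' Map points with a rigid transform
#' @param pts n x 2 matrix (x, y).
#' @param t a `rigid_transform` (or list with u, v, theta).
#' @param dim c(rows, cols) of the frame defining the rotation center.
#' @return transformed n x 2 matrix.
#' @export
transform_points <- function(pts, t, dim) {
  ctr <- c((dim[2] - 1) / 2, (dim[1] - 1) / 2)
  out <- rotate_points(pts, t$theta, ctr)
  out[, 1] <- out[, 1] + t$u
  out[, 2] <- out[, 2] + t$v
  out
}

#' Compose rigid transforms (apply `first`, then `second`)
#' @param first,second `rigid_transform`s about the same frame center.
#' @return composed `rigid_transform`.
#' @export
compose_rigid <- function(first, second) {
  th2 <- second$theta * pi / 180
  u <- cos(th2) * first$u - sin(th2) * first$v + second$u
  v <- sin(th2) * first$u + cos(th2) * first$v + second$v
  structure(list(u = u, v = v, theta = first$theta + second$theta,
                 gamma = min(first$gamma, second$gamma),
                 frame_index = second$frame_index),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_rigid <- function(t) {
  th <- -t$theta * pi / 180
  structure(list(u = -(cos(th) * t$u - sin(th) * t$v),
                 v = -(sin(th) * t$u + cos(th) * t$v),
                 theta = -t$theta, gamma = t$gamma,
                 frame_index = t$frame_index),
            class = "rigid_transform")
}

#' Normalized correlation between a reference and a transformed frame
#'
#' @param ref,moving numeric matrices of identical shape.
#' @param u,v,theta candidate transform (px, px, degrees).
#' @return gamma in `[-1, 1]`.
#' @export
normalized_correlation <- function(ref, moving, u = 0, v = 0, theta = 0) {
  stopifnot(all(dim(ref) == dim(moving)))
  mov <- if (u == 0 && v == 0 && theta == 0) moving
         else apply_rigid(moving, u, v, theta)
  if (sd(ref) == 0 || sd(mov) == 0) stop("zero variance")
  n <- length(ref)
  num <- sum(ref * mov) - sum(ref) * sum(mov) / n
  den <- sqrt((sum(ref^2) - sum(ref)^2 / n) * (sum(mov^2) - sum(mov)^2 / n))
  num / den
}

#' Register one frame to a reference by grid search + refinement
#'
#' Exhaustive search of gamma over the integer (u, v, theta) grid, then
#' three levels of half-step bisection around the best grid point.
#'
#' @param ref,moving numeric matrices of identical shape.
#' @param search list with `u`, `v` = c(min, max) in px and `theta` =
#'   c(min, max) in degrees; integer/1-degree steps are used for the grid.
#' @param gamma_floor warn "poor alignment" if the best gamma is below this.
#' @param frame_index 0-based index recorded on the result.
#' @return a `rigid_transform` with the achieved `gamma`.
#' @export
register_frame <- function(ref, moving,
                           search = list(u = c(-15, 15), v = c(-15, 15),
                                         theta = c(-15, 15)),
                           gamma_floor = 0.5, frame_index = 0L) {
  stopifnot(all(dim(ref) == dim(moving)))
  grid_best <- function(rf, mv, us, vs, thetas, theta_step) {
    ctr <- frame_center(rf)
    best <- list(gamma = -Inf, score = -Inf)
    for (th in thetas) {
      rot <- if (th == 0) mv
             else cpp_rigid_transform(mv, 0, 0, th * pi / 180, ctr[1], ctr[2])
      gg <- cpp_gamma_shift_grid(rf, rot, as.integer(us[1]),
                                 as.integer(us[2]), as.integer(vs[1]),
                                 as.integer(vs[2]))
      top <- suppressWarnings(max(gg, na.rm = TRUE))
      if (!is.finite(top)) next
      # gamma can plateau (e.g. a uniform tube is translation-invariant
      # along its axis while it grows): among near-ties prefer the
      # smallest transform
      cand <- which(gg >= top - 1e-4)
      vi <- (cand - 1) %% nrow(gg) + 1
      ui <- (cand - 1) %/% nrow(gg) + 1
      uu <- us[1] + ui - 1
      vv <- vs[1] + vi - 1
      j <- which.min(uu^2 + vv^2)
      score <- top - 1e-6 * (uu[j]^2 + vv[j]^2 + th^2)
      if (score > best$score) {
        best <- list(u = uu[j], v = vv[j], theta = th, gamma = gg[cand[j]],
                     score = score)
      }
    }
    best
  }
  # coarse-to-fine: block-averaged quarter resolution locates the optimum,
  # a narrow full-resolution grid sharpens it to 1 px / 1 degree
  f <- max(1L, min(4L, floor(min(dim(ref)) / 48)))
  th_grid <- seq(ceiling(search$theta[1]), floor(search$theta[2]),
                 by = if (f > 1) 2 else 1)
  if (f > 1) {
    best <- grid_best(downsample(ref, f), downsample(moving, f),
                      c(floor(search$u[1] / f), ceiling(search$u[2] / f)),
                      c(floor(search$v[1] / f), ceiling(search$v[2] / f)),
                      th_grid, 2)
    if (!is.finite(best$gamma)) stop("registration failed: zero variance")
    best <- grid_best(ref, moving,
                      pmax(ceiling(search$u[1]),
                           pmin(floor(search$u[2]),
                                best$u * f + c(-f - 1, f + 1))),
                      pmax(ceiling(search$v[1]),
                           pmin(floor(search$v[2]),
                                best$v * f + c(-f - 1, f + 1))),
                      seq(max(ceiling(search$theta[1]), best$theta - 2),
                          min(floor(search$theta[2]), best$theta + 2), by = 1),
                      1)
  } else {
    best <- grid_best(ref, moving,
                      c(ceiling(search$u[1]), floor(search$u[2])),
                      c(ceiling(search$v[1]), floor(search$v[2])),
                      th_grid, 1)
  }
  if (!is.finite(best$gamma)) stop("registration failed: zero variance")
  # bisection refinement: half the step at each of 3 levels
  step <- c(1, 1, 1) / 2
  for (level in 1:3) {
    for (du in c(-1, 0, 1)) for (dv in c(-1, 0, 1)) for (dth in c(-1, 0, 1)) {
      if (du == 0 && dv == 0 && dth == 0) next
      uu <- best$u + du * step[1]
      vv <- best$v + dv * step[2]
      tt <- best$theta + dth * step[3]
      g <- normalized_correlation(ref, moving, uu, vv, tt)
      # require a real improvement so plateau drift cannot accumulate
      if (g > best$gamma + 1e-7)
        best <- list(u = uu, v = vv, theta = tt, gamma = g)
    }
    step <- step / 2
  }
  if (best$gamma < gamma_floor)
    warning(sprintf("poor alignment at frame %d (gamma = %.3f)", frame_index,
                    best$gamma))
  structure(c(best[c("u", "v", "theta", "gamma")],
              list(frame_index = as.integer(frame_index))),
            class = "rigid_transform")
}

#' Rigidly align an image sequence to a reference frame
#'
#' By default registers each frame to its predecessor (successive frames
#' differ minimally even while the cell grows) and composes the chain to
#' the reference; direct-to-reference registration is available. The same
#' per-frame transform is applied to every channel.
#'
#' @param seq an [image_sequence()].
#' @param reference_index 0-based reference frame (default 0).
#' @param channel channel driving the registration (default first).
#' @param strategy `"successive"` (default) or `"direct"`.
#' @param search,gamma_floor passed to [register_frame()].
#' @param use_mask if TRUE, register on Otsu masks of the channel instead of
#'   raw intensities (suppresses intracellular signal changes).
#' @param polarity mask polarity when `use_mask` is TRUE.
#' @return list with `seq` (aligned [image_sequence()]) and `transforms`
#'   (list of `rigid_transform`, one per frame; identity at the reference).
#' @export
normalize_sequence <- function(seq, reference_index = 0L, channel = 1,
                               strategy = c("successive", "direct"),
                               search = list(u = c(-15, 15), v = c(-15, 15),
                                             theta = c(-15, 15)),
                               gamma_floor = 0.5, use_mask = FALSE,
                               polarity = "bright_object") {
  strategy <- match.arg(strategy)
  nf <- n_frames(seq)
  stopifnot(reference_index >= 0, reference_index < nf)
  frames <- seq$channels[[channel]]
  if (use_mask)
    frames <- lapply(seq_len(nf), function(i)
      binarize_otsu(frames[[i]], polarity, i - 1L)$grid * 1)
  transforms <- vector("list", nf)
  transforms[[reference_index + 1]] <- rigid_identity(reference_index)
  if (strategy == "direct") {
    ref <- frames[[reference_index + 1]]
    for (i in seq_len(nf)) {
      if (i == reference_index + 1) next
      transforms[[i]] <- register_frame(ref, frames[[i]], search, gamma_floor,
                                        i - 1L)
    }
  } else {
    # successive chain outward from the reference in both directions
    if (reference_index + 2 <= nf) {
      for (i in (reference_index + 2):nf) {
        step <- register_frame(frames[[i - 1]], frames[[i]], search,
                               gamma_floor, i - 1L)
        transforms[[i]] <- compose_rigid(step, transforms[[i - 1]])
        transforms[[i]]$frame_index <- i - 1L
      }
    }
    if (reference_index > 0) {
      for (i in seq(reference_index, 1)) {
        step <- register_frame(frames[[i + 1]], frames[[i]], search,
                               gamma_floor, i - 1L)
        transforms[[i]] <- compose_rigid(step, transforms[[i + 1]])
        transforms[[i]]$frame_index <- i - 1L
      }
    }
  }
  aligned <- lapply(seq$channels, function(ch)
    lapply(seq_len(nf), function(i) {
      t <- transforms[[i]]
      if (t$u == 0 && t$v == 0 && t$theta == 0) ch[[i]]
      else apply_rigid(ch[[i]], t$u, t$v, t$theta)
    }))
  out <- seq
  out$channels <- aligned
  list(seq = out, transforms = transforms)
}

#' Transforms as a data frame
#' @param transforms list of `rigid_transform`.
#' @return data.frame (frame, u, v, theta_deg, gamma).
#' @export
transforms_table <- function(transforms) {
  do.call(rbind, lapply(transforms, function(t)
    data.frame(frame = t$frame_index, u = t$u, v = t$v, theta_deg = t$theta,
               gamma = t$gamma)))
}
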