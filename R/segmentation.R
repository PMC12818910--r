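# Segmentation: one binary mask per frame (Otsu baseline or externally
# supplied masks), then a single smooth closed subpixel contour per mask.
# Deep-learning segmentation is deliberately out of scope: the pipeline's
# contract starts at masks, and any external tool (e.g. a promptable
# segmentation model) can feed masks in via load_masks().

otsu_threshold <- function(frame, n_bins = 256L) {
  rng <- range(frame, finite = TRUE)
  if (diff(rng) == 0) stop("no threshold separates foreground")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(frame, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

finalize_mask <- function(grid, frame_index) {
  if (!any(grid)) stop("no foreground in frame ", frame_index)
  cc <- cpp_largest_component(grid)
  if (cc$n_components > 1)
    warning(sprintf("frame %d: %d foreground components; keeping largest",
                    frame_index, cc$n_components))
  grid <- cpp_fill_holes(cc$mask)
  nr <- nrow(grid); nc <- ncol(grid)
  if (any(grid[1, ]) || any(grid[nr, ]) || any(grid[, 1]) || any(grid[, nc]))
    warning("frame ", frame_index, ": foreground touches the image border")
  structure(list(grid = grid, frame_index = as.integer(frame_index)),
            class = "binary_mask")
}

#' Binarize a frame by global Otsu thresholding
#'
#' Computes the Otsu threshold (maximal between-class variance on a 256-bin
#' histogram), keeps the largest connected component and fills interior
#' holes.
#'
#' @param frame numeric intensity matrix.
#' @param polarity `"bright_object"` (fluorescence; foreground above the
#'   threshold) or `"dark_object"` (bright-field).
#' @param frame_index 0-based index recorded on the mask.
#' @return a `binary_mask` (fields `grid`, `frame_index`).
#' @export
binarize_otsu <- function(frame, polarity = c("bright_object", "dark_object"),
                          frame_index = 0L) {
  polarity <- match.arg(polarity)
  thr <- otsu_threshold(frame)
  grid <- if (polarity == "bright_object") frame > thr else frame < thr
  finalize_mask(grid, frame_index)
}

#' Load externally generated binary masks
#'
#' Ingests per-frame masks (e.g. exported from a promptable segmentation
#' model) from a multi-page TIFF or a vector of single-page image paths.
#' Nonzero pixels are foreground. Each mask is validated the same way as
#' [binarize_otsu()] output: single component, holes filled.
#'
#' @param paths one multi-page TIFF path, or one path per frame (natural
#'   sort order is the caller's responsibility; see [read_sequence()]).
#' @param n_frames expected frame count.
#' @param shape expected c(rows, cols), or NULL to skip the check.
#' @return list of `binary_mask` objects.
#' @export
load_masks <- function(paths, n_frames, shape = NULL) {
  pages <- list()
  for (p in paths) {
    fr <- read_tiff(p)
    for (m in fr) pages[[length(pages) + 1]] <- m
    if (!is.null(shape) && any(dim(fr[[1]]) != shape))
      stop("mask shape mismatch in ", p)
  }
  if (length(pages) != n_frames)
    stop("expected ", n_frames, " masks, got ", length(pages), " from ",
         paste(paths, collapse = ", "))
  lapply(seq_along(pages), function(i)
    finalize_mask(pages[[i]] != 0, i - 1L))
}

#' Extract the subpixel outer contour of a mask
#'
#' Marching-squares iso-contour of the \{0,1\} grid at level 0.5 with linear
#' interpolation, so the boundary is subpixel rather than a pixel
#' staircase (the downstream Voronoi skeleton is highly sensitive to
#' contour noise). The largest closed contour is returned, oriented CCW and
#' resampled to uniform arc-length spacing.
#'
#' @param mask a `binary_mask`.
#' @param spacing resampling spacing in pixels (default 1).
#' @return a [cell_contour()].
#' @export
extract_contour <- function(mask, spacing = 1) {
  grid <- mask$grid
  if (sum(grid) < 10) stop("degenerate mask (area < 10 px)")
  nr <- nrow(grid); nc <- ncol(grid)
  padded <- matrix(0, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- grid * 1
  # contourLines' x runs over rows of z; transpose so x = column coord
  cl <- contourLines(x = seq(-1, nc), y = seq(-1, nr), z = t(padded),
                     levels = 0.5)
  if (length(cl) == 0) stop("no contour found")
  areas <- vapply(cl, function(cc) abs(polygon_area(cbind(cc$x, cc$y))), 1)
  best <- cl[[which.max(areas)]]
  pts <- cbind(best$x, best$y)
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  pts <- resample_closed(pts, spacing)
  cell_contour(pts, mask$frame_index)
}

#' Smooth a contour by locally weighted regression
#'
#' Applies lowess to x(s) and y(s) against cumulative arc length s, with
#' periodic padding so the closure point is not a discontinuity. If the
#' smoothed polygon self-intersects, the span is halved (with a warning)
#' down to a floor of 0.02.
#'
#' @param contour a [cell_contour()].
#' @param frac lowess span as a fraction of points, in (0, 1].
#' @return a smoothed [cell_contour()].
#' @export
smooth_contour <- function(contour, frac = 0.05) {
  stopifnot(frac > 0, frac <= 1)
  pts <- contour$points
  n <- nrow(pts)
  pad <- ceiling(n / 4)
  idx <- c((n - pad + 1):n, 1:n, 1:pad)
  closed <- rbind(pts, pts[1, ])
  total <- arc_length(closed)[n + 1]
  s <- arc_length(closed)[1:n]
  s_pad <- c(s[(n - pad + 1):n] - total, s, s[1:pad] + total)
  repeat {
    f_eff <- frac * n / length(idx)  # span measured on the unpadded contour
    sx <- lowess(s_pad, pts[idx, 1], f = f_eff)$y
    sy <- lowess(s_pad, pts[idx, 2], f = f_eff)$y
    out <- cbind(sx[(pad + 1):(pad + n)], sy[(pad + 1):(pad + n)])
    if (!polygon_self_intersects(out))
      return(cell_contour(resample_closed(out, 1), contour$frame_index))
    if (frac <= 0.02)
      stop("contour smoothing failed: self-intersection at minimum span")
    frac <- frac / 2
    warning("smoothed contour self-intersects; retrying with frac = ", frac)
  }
}

#' Write contours to CSV
#' @param contours list of [cell_contour()].
#' @param path output CSV (columns frame, vertex_index, x, y).
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  rows <- do.call(rbind, lapply(contours, function(cc)
    data.frame(frame = cc$frame_index,
               vertex_index = seq_len(nrow(cc$points)) - 1L,
               x = cc$points[, 1], y = cc$points[, 2])))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
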