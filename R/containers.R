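#' Image sequence container
#'
#' Ordered stack of 2-D intensity frames with physical calibration. One or
#' more channels, each a list of numeric matrices of identical shape.
#'
#' @param channels named list of channels; each channel is a list of
#'   numeric matrices (rows x cols). A single matrix list is accepted and
#'   becomes channel `"main"`.
#' @param pixel_size pixel size, micrometers per pixel.
#' @param dt frame interval, in `time_unit`s.
#' @param time_unit label for the time axis (default `"min"`).
#' @return an `image_sequence` object.
#' @export
image_sequence <- function(channels, pixel_size, dt, time_unit = "min") {
  if (is.matrix(channels)) channels <- list(main = list(channels))
  if (!is.list(channels)) stop("channels must be a list")
  if (is.matrix(channels[[1]])) channels <- list(main = channels)
  if (is.null(names(channels)))
    names(channels) <- paste0("ch", seq_along(channels) - 1)
  nf <- vapply(channels, length, 1L)
  if (length(unique(nf)) != 1)
    stop("all channels must have the same number of frames")
  dims <- unique(unlist(lapply(channels, function(ch) lapply(ch, dim)),
                        recursive = FALSE))
  if (length(unique(lapply(dims, identity))) != 1)
    stop("all frames must have identical shape")
  stopifnot(pixel_size > 0, dt > 0)
  structure(list(channels = channels, pixel_size = pixel_size, dt = dt,
                 time_unit = time_unit),
            class = "image_sequence")
}

#' Number of frames in an image sequence
#' @param seq an `image_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$channels[[1]])

#' Fetch one frame of one channel
#' @param seq an `image_sequence`.
#' @param frame 0-based frame index.
#' @param channel channel name or index (default first).
#' @return numeric matrix.
#' @export
get_frame <- function(seq, frame, channel = 1) {
  seq$channels[[channel]][[frame + 1]]
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$channels[[1]][[1]])
  cat(sprintf(
    "<image_sequence> %d frame(s), %d x %d px, channels: %s\n  pixel_size = %g um/px, dt = %g %s\n",
    n_frames(x), d[1], d[2], paste(names(x$channels), collapse = ", "),
    x$pixel_size, x$dt, x$time_unit))
  invisible(x)
}

#' Closed cell contour
#'
#' Ordered subpixel boundary polygon of one cell in one frame. Vertices are
#' (x, y) with x = column, y = row, 0-based; the first vertex is not
#' repeated at the end; orientation is CCW (signed shoelace area > 0).
#'
#' @param points n x 2 numeric matrix.
#' @param frame_index 0-based frame index.
#' @param validate check the polygon invariants (default TRUE).
#' @return a `cell_contour` object.
#' @export
cell_contour <- function(points, frame_index = 0L, validate = TRUE) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y")
  if (validate) {
    if (nrow(points) < 16) stop("contour must have at least 16 points")
    a <- polygon_area(points)
    if (a < 0) {
      points <- points[nrow(points):1, , drop = FALSE]
      a <- -a
    }
    if (a <= 0) stop("contour must enclose positive area")
  }
  structure(list(points = points, frame_index = as.integer(frame_index)),
            class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat(sprintf("<cell_contour> frame %d: %d vertices, area %.1f px^2\n",
              x$frame_index, nrow(x$points), polygon_area(x$points)))
  invisible(x)
}

#' @export
print.cell_centerline <- function(x, ...) {
  cat(sprintf(
    "<cell_centerline> frame %d: %d points, L = %.2f um%s\n",
    x$frame_index, nrow(x$points), max(x$s_um),
    if (isTRUE(x$oriented)) " (bottom -> tip)" else " (unoriented)"))
  invisible(x)
}
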