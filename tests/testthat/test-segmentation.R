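disk_image <- function(n = 80, r = 15, fg = 200, bg = 10) {
  ctr <- (n - 1) / 2
  d <- outer(0:(n - 1), 0:(n - 1),
             function(row, col) sqrt((col - ctr)^2 + (row - ctr)^2))
  matrix(ifelse(d <= r, fg, bg), n, n)
}

test_that("Otsu recovers an ideal disk and rejects constant images", {
  img <- disk_image()
  m <- binarize_otsu(img)
  ideal <- img > 100
  agreement <- mean(m$grid == ideal)
  expect_gte(agreement, 0.99)
  expect_error(binarize_otsu(matrix(7, 10, 10)), "no threshold")
})

test_that("Otsu threshold sits strictly between the two levels of a bimodal image", {
  img <- matrix(10, 20, 20)
  img[5:15, 5:15] <- 200
  thr <- tipgrow:::otsu_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
})

test_that("Otsu masks are invariant to positive affine intensity rescaling", {
  set.seed(3)
  img <- disk_image() + matrix(rnorm(6400, 0, 5), 80, 80)
  # noise specks may trigger the multi-component cleanup warning; that is
  # incidental to the invariance under test
  m1 <- suppressWarnings(binarize_otsu(img))
  m2 <- suppressWarnings(binarize_otsu(3.7 * img + 40))
  expect_identical(m1$grid, m2$grid)
})

test_that("dark_object polarity selects the dark side", {
  img <- 210 - disk_image()
  m <- binarize_otsu(img, "dark_object")
  expect_gte(mean(m$grid == (img < 100)), 0.99)
})

test_that("mask cleanup keeps the largest component and fills holes", {
  img <- matrix(10, 60, 60)
  img[10:40, 10:40] <- 200
  img[20:30, 20:30] <- 10        # interior hole
  img[50:55, 50:55] <- 200       # smaller second component
  expect_warning(m <- binarize_otsu(img), "components")
  expect_true(all(m$grid[20:30, 20:30]))   # hole filled
  expect_false(any(m$grid[50:55, 50:55]))  # small component dropped
})

test_that("external masks round-trip through load_masks and are validated", {
  masks <- list(matrix(0, 40, 40), matrix(0, 40, 40))
  masks[[1]][10:30, 15:25] <- 1
  masks[[2]][12:32, 15:25] <- 1
  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff(masks, p, bits = 8L)
  loaded <- load_masks(p, 2, shape = c(40, 40))
  expect_identical(loaded[[1]]$grid, masks[[1]] == 1)
  expect_error(load_masks(p, 3), "expected 3 masks")
  expect_error(load_masks(p, 2, shape = c(50, 40)), "shape mismatch")
  empty <- withr::local_tempfile(fileext = ".tif")
  write_tiff(matrix(0, 40, 40), empty, bits = 8L)
  expect_error(load_masks(empty, 1), "no foreground")
})

test_that("extract_contour is subpixel, CCW, and recovers simple shapes", {
  sq <- matrix(10, 60, 60)
  sq[21:40, 21:40] <- 200
  cc <- extract_contour(binarize_otsu(sq))
  expect_gt(polygon_area(cc$points), 0)               # CCW convention
  expect_lt(abs(polygon_area(cc$points) - 400) / 400, 0.02)

  cc2 <- extract_contour(binarize_otsu(disk_image()))
  per <- max(arc_length(rbind(cc2$points, cc2$points[1, ])))
  # rasterized disk boundary sits half a pixel outside the pixel centers
  expect_lt(abs(per - 2 * pi * 15.5) / (2 * pi * 15.5), 0.03)
  expect_gte(nrow(cc2$points), 16)
  tiny <- structure(list(grid = matrix(FALSE, 10, 10), frame_index = 0L),
                    class = "binary_mask")
  tiny$grid[5, 5:6] <- TRUE
  expect_error(extract_contour(tiny), "degenerate")
})

test_that("contour smoothing rounds corners, preserves area, and is gentle on smooth input", {
  sq <- matrix(10, 60, 60)
  sq[21:40, 21:40] <- 200
  cc <- extract_contour(binarize_otsu(sq))
  sm <- smooth_contour(cc, 0.1)
  expect_lt(max(discrete_curvature(sm$points)),
            max(discrete_curvature(cc$points)))

  disk <- extract_contour(binarize_otsu(disk_image()))
  smd <- smooth_contour(disk, 0.1)
  expect_lt(abs(polygon_area(smd$points) - polygon_area(disk$points)) /
              polygon_area(disk$points), 0.05)

  th <- seq(0, 2 * pi, length.out = 200)[-200]
  ell <- cell_contour(cbind(40 + 30 * cos(th), 40 + 18 * sin(th)))
  sme <- smooth_contour(ell, 0.02)
  d <- tipgrow:::cpp_dist_to_polyline(
    sme$points[, 1], sme$points[, 2],
    c(ell$points[, 1], ell$points[1, 1]),
    c(ell$points[, 2], ell$points[1, 2]))
  expect_lt(max(d[, 1]), 0.5)
})

test_that("capsule area from the analytic fixture is recovered within 2%", {
  for (w_px in c(12, 20)) {
    spec <- synthetic_cell_spec(n_frames = 2, frame_shape = c(150, 110),
                                width = w_px * 0.2, initial_length = 16 * 0.2 + w_px * 0.2,
                                growth_rate = 0, jitter_translation_sd = 0,
                                jitter_rotation_sd = 0, noise_sd = 0)
    mv <- make_growing_cell(spec)
    cc <- extract_contour(binarize_otsu(get_frame(mv$seq, 0)))
    true_area <- 16 * w_px + pi * (w_px / 2)^2  # rectangle + two half disks
    expect_lt(abs(polygon_area(cc$points) - true_area) / true_area, 0.02)
  }
})
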