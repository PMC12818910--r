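band_movie <- function(n_frames = 4, rel = 0.6, offset = NULL, ...) {
  make_growing_cell(synthetic_cell_spec(
    n_frames = n_frames, band_center_rel = rel,
    band_offset_from_tip = offset, jitter_translation_sd = 0,
    jitter_rotation_sd = 0, noise_sd = 0, ...))
}

frame_profile <- function(mv, f, step = 0.5) {
  m <- binarize_otsu(get_frame(mv$seq, f), frame_index = f)
  cc <- extract_contour(m)
  cl <- centerline_of_frame(mv, f)
  profile_along_centerline(get_frame(mv$seq, f, "signal"), cl, step = step,
                           contour = cc)
}

test_that("profile of a uniform cell is flat at the interior intensity", {
  mv <- make_growing_cell(small_spec(n_frames = 2))
  cl <- centerline_of_frame(mv, 0)
  cc <- extract_contour(binarize_otsu(get_frame(mv$seq, 0)))
  p <- profile_along_centerline(get_frame(mv$seq, 0), cl, step = 0.5,
                                contour = cc)
  # away from the AA boundary ring at the two extreme samples
  core <- p$intensity[3:(length(p$intensity) - 3)]
  expect_true(all(abs(core - 200) / 200 < 0.01))
  expect_equal(p$s_um[1], 0)
  expect_lt(abs(max(p$s_um) - max(cl$s_um)), 0.5)
  expect_error(profile_along_centerline(get_frame(mv$seq, 0), cl, step = 50,
                                        contour = cc), "step")
})

test_that("band argmax lands within 2 steps of the programmed center", {
  mv <- band_movie(rel = 0.6)
  for (f in c(0, 3)) {
    p <- frame_profile(mv, f)
    mu_true <- mv$truth$table$band_mu_um[f + 1]
    expect_lt(abs(p$s_um[which.max(p$intensity)] - mu_true), 2 * 0.5)
  }
})

test_that("oversized halfwidth is clipped at the contour", {
  mv <- band_movie()
  cl <- centerline_of_frame(mv, 0)
  cc <- extract_contour(binarize_otsu(get_frame(mv$seq, 0)))
  img <- get_frame(mv$seq, 0, "signal")
  wide <- profile_along_centerline(img, cl, halfwidth = 10, step = 0.5,
                                   contour = cc)
  clipped <- profile_along_centerline(img, cl, halfwidth = 1.45, step = 0.5,
                                      contour = cc)
  mid <- 5:(length(wide$intensity) - 5)
  expect_equal(wide$intensity[mid], clipped$intensity[mid], tolerance = 0.05)
})

test_that("kymograph columns replicate the per-frame profiles", {
  mv <- band_movie()
  profiles <- lapply(0:3, function(f) frame_profile(mv, f))
  ky <- build_kymograph(profiles, "bottom", dt = 10)
  for (j in 1:4) {
    n <- length(profiles[[j]]$intensity)
    expect_equal(ky$matrix[seq_len(n), j], profiles[[j]]$intensity,
                 tolerance = 1e-9)
    expect_true(all(is.na(ky$matrix[-seq_len(n + 1), j])))
  }
})

test_that("a static cell with a static band gives identical kymograph columns", {
  mv <- band_movie(rel = 0.5, growth_rate = 0)
  profiles <- lapply(0:3, function(f) frame_profile(mv, f))
  ky <- build_kymograph(profiles, "bottom", dt = 10)
  for (j in 2:4) expect_equal(ky$matrix[, j], ky$matrix[, 1])
})

test_that("a tip-fixed band is a horizontal ridge in a tip-anchored kymograph", {
  mv <- band_movie(rel = NULL, offset = 4, n_frames = 6)
  profiles <- lapply(0:5, function(f) frame_profile(mv, f))
  ky_tip <- build_kymograph(profiles, "tip", dt = 10)
  ridge <- apply(ky_tip$matrix, 2, function(col) ky_tip$s_axis[which.max(col)])
  expect_lt(sd(ridge) / 0.5, 2)              # ridge SD under 2 bins
  expect_lt(abs(mean(ridge) - 4), 2 * 0.5)
  # bottom-anchored: the same ridge tracks L(t) - 4
  ky_bot <- build_kymograph(profiles, "bottom", dt = 10)
  ridge_b <- apply(ky_bot$matrix, 2, function(col)
    ky_bot$s_axis[which.max(col)])
  expect_true(all(abs(ridge_b - (mv$truth$table$L_um - 4)) < 1))
})

test_that("noise-free Gaussian profiles are recovered within 1%", {
  prof <- list(s_um = seq(0, 60, by = 0.25),
               intensity = 10 + 100 * exp(-(seq(0, 60, by = 0.25) - 30)^2 /
                                            (2 * 4^2)),
               L_um = 60, frame_index = 0L, step = 0.25)
  fit <- fit_truncated_gaussian(prof)
  expect_lt(abs(fit$A - 100) / 100, 0.01)
  expect_lt(abs(fit$mu - 30) / 30, 0.01)
  expect_lt(abs(fit$sigma - 4) / 4, 0.01)
  expect_lt(abs(fit$B - 10) / 10, 0.01)
  expect_equal(fit$upper - fit$lower, 2 * fit$sigma)
  flat <- list(s_um = 0:50, intensity = rep(7, 51), L_um = 50,
               frame_index = 0L, step = 1)
  expect_error(fit_truncated_gaussian(flat), "no band detected")
})

test_that("Monte-Carlo band recovery: mu within 0.5 um, sigma within 15%, low bias", {
  mus <- sigmas <- numeric(20)
  for (s in 1:20) {
    y <- make_band_profile(240, center = 120, sigma = 16, amplitude = 100,
                           baseline = 10, noise_sd = 5, seed = s)
    prof <- list(s_um = (0:239) * 0.25, intensity = y, L_um = 59.75,
                 frame_index = 0L, step = 0.25)
    fit <- fit_truncated_gaussian(prof)
    mus[s] <- fit$mu
    sigmas[s] <- fit$sigma
  }
  expect_lt(median(abs(mus - 30)), 0.5)
  expect_lt(median(abs(sigmas - 4)) / 4, 0.15)
  expect_lt(abs(mean(mus) - 30), 0.1)    # bias
})

test_that("track_band follows a moving nucleus and tolerates corrupt frames", {
  mv <- band_movie(rel = 0.6, n_frames = 6)
  profiles <- lapply(0:5, function(f) frame_profile(mv, f))
  tab <- track_band(profiles, dt = 10)
  mu_true <- mv$truth$table$band_mu_um
  expect_true(all(abs(tab$mu_um - mu_true) < 0.5))
  true_rate <- coef(lm(mu_true ~ tab$time))[2]
  fit_rate <- coef(lm(tab$mu_um ~ tab$time))[2]
  expect_lt(abs(fit_rate - true_rate) / true_rate, 0.1)

  profiles[[3]]$intensity[] <- 0
  tab2 <- track_band(profiles, dt = 10)
  expect_true(is.na(tab2$mu_um[3]))
  expect_false(any(is.na(tab2$mu_um[-3])))
  bad <- lapply(profiles, function(p) { p$intensity[] <- 0; p })
  expect_error(track_band(bad), "every frame")
})

test_that("kymograph export encodes missing cells as NaN/blank, never zero", {
  mv <- band_movie()
  profiles <- lapply(0:3, function(f) frame_profile(mv, f))
  ky <- build_kymograph(profiles, "bottom", dt = 10)
  dir <- withr::local_tempdir()
  write_kymograph(ky, dir)
  tif <- read_tiff(file.path(dir, "kymograph.tif"))[[1]]
  expect_true(any(is.nan(tif)))
  expect_false(any(tif[is.nan(ky$matrix)] == 0, na.rm = TRUE))
  csv <- read.csv(file.path(dir, "kymograph.csv"))
  expect_true(anyNA(csv$intensity))
})
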