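fixture_frame <- function(seed = 1, noise = 0) {
  mv <- make_growing_cell(small_spec(n_frames = 2, noise_sd = noise,
                                     seed = seed))
  get_frame(mv$seq, 0)
}

test_that("gamma is 1 for self-correlation and -1 for an inverted image", {
  f <- fixture_frame()
  expect_equal(normalized_correlation(f, f), 1)
  inv <- -(f - mean(f)) + mean(f)
  expect_equal(normalized_correlation(f, inv), -1)
  expect_error(normalized_correlation(f, matrix(5, nrow(f), ncol(f))),
               "zero variance")
})

test_that("gamma at the aligning transform of a shifted copy is within 0.02 of 1", {
  f <- fixture_frame()
  shifted <- apply_rigid(f, 3, -2, 0)   # content moved by (+3, -2)
  expect_gt(normalized_correlation(f, shifted, -3, 2, 0), 0.98)
})

test_that("gamma is invariant to positive affine intensity rescaling", {
  f <- fixture_frame()
  mov <- apply_rigid(f, 2, 1, 3)
  # full affine a*I + b at a fixed identity transform (no zero-fill)
  g1 <- normalized_correlation(f, mov)
  expect_lt(abs(g1 - normalized_correlation(f, 2.3 * mov + 17)), 1e-6)
  expect_lt(abs(g1 - normalized_correlation(0.4 * f + 90, mov)), 1e-6)
  # pure rescaling a*I commutes with the zero-fill of a nonzero transform
  g2 <- normalized_correlation(f, mov, -1.5, 0.5, -2)
  expect_lt(abs(g2 - normalized_correlation(f, 2.3 * mov, -1.5, 0.5, -2)),
            1e-6)
})

test_that("register_frame recovers a known rigid transform within half a pixel/degree", {
  f <- fixture_frame()
  mov <- apply_rigid(f, 4, 1, 5)
  tr <- register_frame(f, mov)
  # registering the transformed copy finds the inverse transform
  inv <- invert_rigid(structure(list(u = 4, v = 1, theta = 5, gamma = 1,
                                     frame_index = 0L),
                                class = "rigid_transform"))
  expect_lt(abs(tr$u - inv$u), 0.5)
  expect_lt(abs(tr$v - inv$v), 0.5)
  expect_lt(abs(tr$theta - inv$theta), 0.5)
  id <- register_frame(f, f)
  expect_equal(c(id$u, id$v, id$theta), c(0, 0, 0))
  expect_gte(id$gamma, 0.999)
})

test_that("median recovery error over seeded jitters is within (0.5 px, 0.5 px, 0.5 deg)", {
  f <- fixture_frame()
  set.seed(11)
  errs <- t(replicate(8, {
    u <- runif(1, -10, 10); v <- runif(1, -10, 10); th <- runif(1, -10, 10)
    mov <- apply_rigid(f, u, v, th)
    tr <- register_frame(f, mov)
    inv <- invert_rigid(structure(list(u = u, v = v, theta = th, gamma = 1,
                                       frame_index = 0L),
                                  class = "rigid_transform"))
    abs(c(tr$u - inv$u, tr$v - inv$v, tr$theta - inv$theta))
  }))
  expect_lt(median(errs[, 1]), 0.5)
  expect_lt(median(errs[, 2]), 0.5)
  expect_lt(median(errs[, 3]), 0.5)
})

test_that("applying a recovered transform then its inverse returns the frame", {
  f <- fixture_frame()
  mov <- apply_rigid(f, 3, -4, 6)
  back <- apply_rigid(mov, invert_rigid(structure(
    list(u = 3, v = -4, theta = 6, gamma = 1, frame_index = 0L),
    class = "rigid_transform"))$u,
    invert_rigid(structure(list(u = 3, v = -4, theta = 6, gamma = 1,
                                frame_index = 0L),
                           class = "rigid_transform"))$v, -6)
  interior <- abs(back - f)[20:130, 20:90]
  expect_lt(mean(interior), 0.01 * diff(range(f)))
})

test_that("normalize_sequence aligns a jittered growth-free movie", {
  mv <- make_growing_cell(small_spec(n_frames = 4, growth_rate = 0,
                                     jitter_translation_sd = 4,
                                     jitter_rotation_sd = 3, seed = 3))
  out <- normalize_sequence(mv$seq)
  tt <- mv$truth$table
  for (f in 1:3) {
    tr <- out$transforms[[f + 1]]
    inv <- invert_rigid(structure(list(u = tt$u[f + 1], v = tt$v[f + 1],
                                       theta = tt$theta_deg[f + 1],
                                       gamma = 1, frame_index = f),
                                  class = "rigid_transform"))
    expect_lt(abs(tr$u - inv$u), 1)
    expect_lt(abs(tr$v - inv$v), 1)
    expect_lt(abs(tr$theta - inv$theta), 1)
    g <- normalized_correlation(get_frame(out$seq, 0),
                                get_frame(out$seq, f))
    expect_gte(g, 0.98)
  }
  # identical frames register to identity
  const <- image_sequence(list(main = rep(list(get_frame(mv$seq, 0)), 3)),
                          0.2, 10)
  idt <- normalize_sequence(const)$transforms
  for (t in idt) expect_equal(c(t$u, t$v, t$theta), c(0, 0, 0))
})

test_that("normalization is idempotent within refinement resolution", {
  mv <- make_growing_cell(small_spec(n_frames = 3, growth_rate = 0,
                                     jitter_translation_sd = 4,
                                     jitter_rotation_sd = 2, seed = 5))
  once <- normalize_sequence(mv$seq)
  twice <- normalize_sequence(once$seq)
  for (t in twice$transforms) {
    expect_lte(abs(t$u), 0.5)
    expect_lte(abs(t$v), 0.5)
    expect_lte(abs(t$theta), 0.5)
  }
})
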