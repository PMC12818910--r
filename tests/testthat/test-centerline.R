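rect_contour <- function(w = 200, h = 20) {
  pts <- rbind(cbind(seq(0, w, by = 1), 0),
               cbind(w, seq(1, h, by = 1)),
               cbind(seq(w - 1, 0, by = -1), h),
               cbind(0, seq(h - 1, 1, by = -1)))
  cell_contour(pts)
}

test_that("skeleton of a long thin rectangle follows the midline", {
  sk <- voronoi_skeleton(rect_contour())
  central <- sk$nodes[sk$nodes[, 1] > 20 & sk$nodes[, 1] < 180, , drop = FALSE]
  expect_gt(nrow(central), 50)
  expect_lt(max(abs(central[, 2] - 10)), 1)
})

test_that("a near-circular contour yields a degenerate skeleton error", {
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  disk <- cell_contour(cbind(30 + 20 * cos(th), 30 + 20 * sin(th)))
  expect_error(
    prune_to_centerline(voronoi_skeleton(disk)),
    "degenerate skeleton|over-pruned")
})

test_that("capsule skeleton stays within 2 px of the true axis over the central 80%", {
  cc <- capsule_contour(30, 60, 170, 60, 24)
  sk <- voronoi_skeleton(cc)
  central <- sk$nodes[sk$nodes[, 1] > 30 + 0.1 * 140 &
                      sk$nodes[, 1] < 30 + 0.9 * 140, , drop = FALSE]
  poly <- prune_to_centerline(sk)
  on_path <- poly[poly[, 1] > 44 & poly[, 1] < 156, , drop = FALSE]
  expect_lt(max(abs(on_path[, 2] - 60)), 2)
})

test_that("pruning removes short spurs from a hand-constructed Y skeleton", {
  # two long arms (~100 px) meeting a 5 px spur at a junction
  left <- cbind(seq(-100, -1), 0)
  right <- cbind(seq(1, 100), 0)
  spur <- cbind(c(1.5, 3), c(2.5, 5))
  nodes <- rbind(left, c(0, 0), right, spur)
  n_l <- nrow(left)
  jn <- n_l + 1
  edges <- rbind(cbind(seq_len(n_l - 1), seq_len(n_l - 1) + 1),
                 c(n_l, jn), c(jn, jn + 1),
                 cbind(jn + seq_len(99), jn + seq_len(99) + 1),
                 c(jn, jn + 101), c(jn + 101, jn + 102))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- sqrt(rowSums((nodes[edges[, 1], ] -
                                       nodes[edges[, 2], ])^2))
  sk <- structure(list(nodes = nodes, edges = edges, graph = g,
                       contour = NULL), class = "skeleton_graph")
  path <- prune_to_centerline(sk, min_branch_length = 10)
  expect_equal(nrow(path), 201)          # spur gone, arms intact
  expect_true(all(path[, 2] == 0))
  # a pure path graph passes through unchanged
  straight <- structure(list(
    nodes = rbind(left, c(0, 0), right),
    graph = {
      e <- cbind(seq_len(200), seq_len(200) + 1)
      gg <- igraph::graph_from_edgelist(e, directed = FALSE)
      igraph::E(gg)$weight <- 1
      gg
    }), class = "skeleton_graph")
  expect_equal(nrow(prune_to_centerline(straight, 10)), 201)
})

test_that("longest-path tie-breaks are deterministic", {
  # symmetric cross: two equal longest paths
  nodes <- rbind(c(0, 0), c(-50, 0), c(50, 0), c(0, -50), c(0, 50))
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 50
  sk <- structure(list(nodes = nodes, edges = edges, graph = g,
                       contour = NULL), class = "skeleton_graph")
  p1 <- prune_to_centerline(sk, min_branch_length = 1)
  p2 <- prune_to_centerline(sk, min_branch_length = 1)
  expect_identical(p1, p2)
  # smallest endpoint in (y, x) is chosen: the vertical arm contains y=-50
  expect_true(any(p1[, 2] == -50))
})

test_that("extrapolation hits a straight wall at the perpendicular foot", {
  wall <- cell_contour(rbind(cbind(seq(0, 100), -20), cbind(100, seq(-19, 20)),
                             cbind(seq(99, 0), 20), cbind(0, seq(19, -19))))
  poly <- cbind(seq(10, 90, by = 1), 0)   # ends 10 px short of x=100 wall
  cl <- extrapolate_to_edge(poly, wall, k = 5, pixel_size = 1,
                            smooth_span = 0)
  ends <- cl$points[c(1, nrow(cl$points)), ]
  hit <- ends[which.max(ends[, 1]), ]
  expect_equal(unname(hit), c(100, 0), tolerance = 0.5)
  expect_error(extrapolate_to_edge(poly[1:3, ], wall, k = 5), "fewer points")
})

test_that("capsule tip and bottom are recovered within 1.5 px and L within max(2 px, 2%)", {
  for (p in capsule_family(6)) {
    mv <- family_movie(p)
    cl <- centerline_of_frame(mv, 2)
    tt <- mv$truth$table[3, ]
    expect_lt(sqrt(sum((cl$tip_point - c(tt$tip_x, tt$tip_y))^2)), 1.5)
    expect_lt(abs(max(cl$s_um) - tt$L_um) / 0.2,
              max(2, 0.02 * tt$L_um / 0.2))
  }
})

test_that("centerline endpoints are invariant under rigid rotation of the contour", {
  p <- capsule_family(1)[[1]]
  mv <- family_movie(p)
  cc <- extract_contour(binarize_otsu(get_frame(mv$seq, 2), frame_index = 2))
  cl0 <- extrapolate_to_edge(prune_to_centerline(voronoi_skeleton(cc)), cc)
  ctr <- colMeans(cc$points)
  for (theta in c(30, 115)) {
    rot <- cell_contour(tipgrow:::rotate_points(cc$points, theta, ctr))
    clr <- extrapolate_to_edge(prune_to_centerline(voronoi_skeleton(rot)), rot)
    back <- tipgrow:::rotate_points(
      clr$points[c(1, nrow(clr$points)), ], -theta, ctr)
    orig <- cl0$points[c(1, nrow(cl0$points)), ]
    err <- min(max(sqrt(rowSums((back - orig)^2))),
               max(sqrt(rowSums((back[2:1, ] - orig)^2))))
    expect_lt(err, 1)
  }
})

test_that("orient_centerline follows anchors, previous frames, and errors without either", {
  poly <- cbind(seq(5, 100, length.out = 50), seq(5, 100, length.out = 50))
  cl <- structure(list(points = poly, s_px = arc_length(poly),
                       s_um = arc_length(poly), pixel_size = 1,
                       frame_index = 0L, oriented = FALSE),
                  class = "cell_centerline")
  o <- orient_centerline(cl, anchor = c(0, 0))
  expect_equal(unname(o$bottom_point), c(5, 5))
  expect_equal(unname(o$tip_point), c(100, 100))
  o2 <- orient_centerline(cl, prev = o)
  expect_equal(o2$bottom_point, o$bottom_point)
  # previous frame with flipped orientation flips the assignment
  oflip <- o
  oflip$bottom_point <- o$tip_point
  oflip$tip_point <- o$bottom_point
  o3 <- orient_centerline(cl, prev = oflip)
  expect_equal(unname(o3$bottom_point), c(100, 100))
  expect_error(orient_centerline(cl), "anchor")
})

test_that("Voronoi centerline agrees with the distance-transform ridge", {
  p <- capsule_family(3)[[2]]
  mv <- family_movie(p)
  m <- binarize_otsu(get_frame(mv$seq, 1), frame_index = 1)
  cc <- extract_contour(m)
  poly <- prune_to_centerline(voronoi_skeleton(cc))
  ridge <- medial_ridge(m, cc)
  s <- arc_length(poly)
  central <- poly[s > 0.1 * max(s) & s < 0.9 * max(s), , drop = FALSE]
  d <- tipgrow:::cpp_dist_to_polyline(ridge[, 1], ridge[, 2],
                                      central[, 1], central[, 2])
  dc <- vapply(seq_len(nrow(central)), function(i)
    min(sqrt((ridge[, 1] - central[i, 1])^2 +
             (ridge[, 2] - central[i, 2])^2)), 1)
  expect_lt(mean(dc), 1)
})
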