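# Centerline extraction.
#
# The medial axis of the cell is approximated by the Voronoi diagram of the
# (uniformly resampled) contour point cloud: Voronoi vertices that fall
# strictly inside the contour polygon, connected by the Voronoi edges whose
# endpoints are both interior, form a skeleton graph. Short leaf branches
# (spurs caused by contour noise) are pruned; the centerline is the longest
# remaining geodesic between two leaves. Because the Voronoi skeleton of a
# capped tube stops roughly half a width short of each end, tip and bottom
# are found by fitting a line through the terminal skeleton points and
# intersecting that ray with the contour.

#' Voronoi skeleton of a cell contour
#'
#' Computes the Delaunay triangulation of the contour points; Voronoi
#' vertices are the triangle circumcenters and Voronoi edges connect
#' circumcenters of triangles sharing an edge. Vertices outside the contour
#' polygon (and edges touching them) are discarded; the largest connected
#' component is returned.
#'
#' @param contour a [cell_contour()], resampled to uniform spacing.
#' @return a `skeleton_graph`: `nodes` (n x 2), `edges` (m x 2 node
#'   indices), `graph` (weighted igraph), `contour`.
#' @export
voronoi_skeleton <- function(contour) {
  pts <- contour$points
  # Triangulate on normalized, deterministically jittered coordinates:
  # uniformly resampled boundaries are full of exactly cocircular quads,
  # which make the incremental triangulation numerically fragile. The
  # jitter (~1e-5 of the bounding box) only disambiguates topology;
  # circumcenters are computed from the original coordinates.
  ctr <- colMeans(pts)
  scale <- max(apply(pts, 2, function(a) diff(range(a))))
  jit <- (((seq_len(nrow(pts)) * 2654435761) %% 9973) / 9973 - 0.5) * 2e-5
  nx <- (pts[, 1] - ctr[1]) / scale + jit
  ny <- (pts[, 2] - ctr[2]) / scale + jit[c(2:length(jit), 1)] * 0.7
  tri <- cpp_delaunay(nx, ny)
  if (nrow(tri) == 0) stop("degenerate skeleton")
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ccx <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  ccy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d

  # Delaunay edges shared by two triangles <-> finite Voronoi edges
  e <- rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
             cbind(tri[, 3], tri[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tri_id <- rep(seq_len(nrow(tri)), 3)
  pair <- split(tri_id, key)
  pair <- pair[lengths(pair) == 2]
  ve <- do.call(rbind, pair)
  if (is.null(ve) || nrow(ve) == 0) stop("degenerate skeleton")

  inside <- cpp_point_in_polygon(ccx, ccy, pts[, 1], pts[, 2])
  if (sum(inside) < 2) stop("degenerate skeleton")
  keep_edge <- inside[ve[, 1]] & inside[ve[, 2]]
  ve <- ve[keep_edge, , drop = FALSE]
  if (nrow(ve) == 0) stop("degenerate skeleton")

  used <- sort(unique(as.vector(ve)))
  remap <- match(ve, used)
  dim(remap) <- dim(ve)
  nodes <- cbind(ccx[used], ccy[used])

  # merge near-duplicate Voronoi vertices (twin circumcenters of formerly
  # cocircular quads) by clustering edges shorter than eps
  eps <- 0.02
  elen <- sqrt((nodes[remap[, 1], 1] - nodes[remap[, 2], 1])^2 +
               (nodes[remap[, 1], 2] - nodes[remap[, 2], 2])^2)
  short <- remap[elen < eps, , drop = FALSE]
  cluster <- seq_len(nrow(nodes))
  if (nrow(short) > 0) {
    gs <- igraph::graph_from_edgelist(short, directed = FALSE)
    gs <- igraph::add_vertices(gs, max(0, nrow(nodes) - igraph::vcount(gs)))
    cluster <- igraph::components(gs)$membership
    nodes <- cbind(tapply(nodes[, 1], cluster, mean),
                   tapply(nodes[, 2], cluster, mean))
    remap <- matrix(cluster[remap], ncol = 2)
  }
  keep <- remap[, 1] != remap[, 2]
  remap <- remap[keep, , drop = FALSE]
  if (nrow(remap) == 0) stop("degenerate skeleton")
  w <- sqrt((nodes[remap[, 1], 1] - nodes[remap[, 2], 1])^2 +
            (nodes[remap[, 1], 2] - nodes[remap[, 2], 2])^2)
  g <- igraph::graph_from_edgelist(remap, directed = FALSE)
  if (igraph::vcount(g) < nrow(nodes))
    g <- igraph::add_vertices(g, nrow(nodes) - igraph::vcount(g))
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)
  main_ids <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, main_ids)
  nodes <- nodes[main_ids, , drop = FALSE]
  if (nrow(nodes) < 2) stop("degenerate skeleton")
  # the medial axis of a simple polygon is a tree: remaining cycles are
  # numerical artifacts, removed by the minimum spanning tree
  g <- igraph::mst(g, weights = igraph::E(g)$weight)
  el <- igraph::as_edgelist(g, names = FALSE)
  structure(list(nodes = nodes, edges = el, graph = g, contour = contour),
            class = "skeleton_graph")
}

# Leaf branch of g starting at leaf node `v`: path up to (excluding) the
# first node of degree >= 3, or the whole path if none.
leaf_branch <- function(g, v, deg) {
  path <- v
  prev <- -1L
  cur <- v
  repeat {
    nb <- as.integer(igraph::neighbors(g, cur))
    nb <- nb[nb != prev]
    if (length(nb) == 0) return(list(nodes = path, junction = NA_integer_))
    nxt <- nb[1]
    if (deg[nxt] >= 3) return(list(nodes = path, junction = nxt))
    prev <- cur
    cur <- nxt
    path <- c(path, cur)
  }
}

#' Prune a skeleton graph to its centerline
#'
#' Iteratively removes leaf branches shorter than `min_branch_length`
#' (graph path length from a degree-1 node to the nearest junction), then
#' returns the longest remaining geodesic between two degree-1 nodes.
#' Ties are broken by the lexicographically smallest endpoint list in
#' (y, x), so the result is deterministic.
#'
#' @param skeleton a `skeleton_graph`.
#' @param min_branch_length pruning threshold, px. Default `NULL` estimates
#'   half the cell width as 2x the mean node-to-contour distance / 2 (spur
#'   branches from boundary noise are shorter than the half-width).
#' @return ordered polyline (n x 2 matrix) from an arbitrary end.
#' @export
prune_to_centerline <- function(skeleton, min_branch_length = NULL) {
  g <- skeleton$graph
  nodes <- skeleton$nodes
  igraph::V(g)$name <- seq_len(nrow(nodes))
  if (is.null(min_branch_length)) {
    cpts <- skeleton$contour$points
    d <- cpp_dist_to_polyline(nodes[, 1], nodes[, 2],
                              c(cpts[, 1], cpts[1, 1]),
                              c(cpts[, 2], cpts[1, 2]))[, 1]
    # slightly above half the cell width: branches inside an end cap are
    # up to one half-width long, so the threshold must clear them. The
    # median node clearance estimates the half-width robustly (the mean
    # is biased low by spur nodes sitting near the boundary).
    min_branch_length <- 1.2 * median(d)
  }
  repeat {
    deg <- igraph::degree(g)
    if (!any(deg >= 3)) break
    leaves <- which(deg == 1)
    if (length(leaves) == 0) break
    removed <- FALSE
    drop_nodes <- integer(0)
    for (v in leaves) {
      br <- leaf_branch(g, v, deg)
      if (is.na(br$junction)) next
      len <- sum(igraph::E(g, path = c(br$nodes, br$junction))$weight)
      if (len < min_branch_length) {
        drop_nodes <- c(drop_nodes, br$nodes)
        removed <- TRUE
      }
    }
    if (!removed) break
    g <- igraph::delete_vertices(g, unique(drop_nodes))
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
    if (igraph::vcount(g) == 0)
      stop("over-pruned; reduce min_branch_length")
  }
  if (igraph::vcount(g) < 2) stop("over-pruned; reduce min_branch_length")
  leaves <- which(igraph::degree(g) == 1)
  if (length(leaves) < 2) {
    # cycle-only graph (should not happen for a medial axis); fail loudly
    stop("skeleton has no endpoints after pruning")
  }
  dm <- igraph::distances(g, v = leaves, to = leaves)
  best <- which(dm == max(dm), arr.ind = TRUE)
  # deterministic tie-break on endpoint coordinates in (y, x)
  orig_id <- as.integer(igraph::V(g)$name)
  if (nrow(best) > 1) {
    keys <- apply(best, 1, function(b) {
      ids <- orig_id[leaves[b]]
      ends <- nodes[ids, , drop = FALSE]
      o <- order(ends[, 2], ends[, 1])
      paste(sprintf("%.6f", t(ends[o, c(2, 1)])), collapse = ",")
    })
    best <- best[order(keys)[1], , drop = FALSE]
  } else best <- best[1, , drop = FALSE]
  sp <- igraph::shortest_paths(g, from = leaves[best[1, 1]],
                               to = leaves[best[1, 2]])$vpath[[1]]
  nodes[orig_id[as.integer(sp)], , drop = FALSE]
}

# Total-least-squares direction through points (principal axis).
tls_direction <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  sv$v[, 1]
}

#' Extend a centerline polyline to the cell edge
#'
#' At each end, fits a total-least-squares line through the `k` terminal
#' points and extends it outward from the terminal point; the new endpoint
#' is the first intersection of that ray with the contour polygon. This is
#' the tip/bottom detection step: the Voronoi skeleton cannot reach the
#' cell edge, so its ends are extrapolated linearly.
#'
#' The discrete Voronoi path zigzags at the contour-sampling scale, which
#' inflates its arc length by a few percent; the body of the returned
#' centerline is therefore conditioned by locally quadratic loess against
#' arc length (`smooth_span`), while the terminal directions are fitted on
#' the raw path (a locally linear smoother would bias the end tangent of a
#' curved axis).
#'
#' @param polyline n x 2 matrix (pruned skeleton path).
#' @param contour a [cell_contour()].
#' @param k minimum number of terminal points for the line fit (>= 2); the
#'   effective fit window grows to the local half-width, the scale over
#'   which the fitted direction is extrapolated.
#' @param pixel_size micrometers per pixel for the arc-length scale.
#' @param smooth_span loess span for the body (0 disables smoothing).
#' @return an (unoriented) `cell_centerline`: `points` (endpoints on the
#'   contour), `s_px`, `s_um`, `pixel_size`, `frame_index`.
#' @export
extrapolate_to_edge <- function(polyline, contour, k = 5, pixel_size = 1,
                                smooth_span = 0.2) {
  n <- nrow(polyline)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("polyline has fewer points than k")
  cpts <- contour$points
  cpoly_x <- c(cpts[, 1], cpts[1, 1])
  cpoly_y <- c(cpts[, 2], cpts[1, 2])
  diam <- 2 * max(sqrt((cpts[, 1] - mean(cpts[, 1]))^2 +
                       (cpts[, 2] - mean(cpts[, 2]))^2))
  # fit on a 1-px uniform resampling of the path; the terminal window
  # adapts to the local half-width (the extrapolation distance), so the
  # direction noise of tightly clustered skeleton nodes does not get
  # amplified on wide cells. `k` is the minimum number of fit points.
  total <- arc_length(polyline)[n]
  rp <- resample_at(polyline, seq(0, total, by = min(1, total / (2 * k))))
  # trim terminal points whose boundary clearance falls below the body
  # half-width: the medial axis of a capped tube keeps clearance ~ r up to
  # the cap center, so lower-clearance tail points are residual stubs of
  # cap branches curving toward boundary corners, and they bias the fit
  clr <- cpp_dist_to_polyline(rp[, 1], rp[, 2], cpoly_x, cpoly_y)[, 1]
  hw_med <- median(clr)
  ok_lo <- which(clr >= 0.92 * hw_med)
  if (length(ok_lo) >= 2 * k) {
    lo <- min(ok_lo); hi <- max(ok_lo)
    if (lo > 1 || hi < nrow(rp)) rp <- rp[lo:hi, , drop = FALSE]
  }
  m <- nrow(rp)
  body <- if (smooth_span > 0) smooth_polyline(rp, smooth_span) else rp
  mb <- nrow(body)
  n_fit <- function(end_pt) {
    hw <- cpp_dist_to_polyline(end_pt[1], end_pt[2], cpoly_x, cpoly_y)[1, 1]
    min(max(k, ceiling(hw)), floor(m / 2))
  }
  fit_dir <- function(term_pts, outward) {
    dirv <- tls_direction(term_pts)
    if (sum(dirv * outward) < 0) dirv <- -dirv
    dirv
  }
  # Two direction estimates with complementary failure modes, averaged:
  # a window-TLS over ~one half-width of raw path (noise-averaged, but it
  # lags the end tangent of a curving axis) and a short TLS on the
  # smoothed body end (curvature-faithful, noisier). Their mean keeps the
  # worst-case tip error clearly below the half-width lever arm's
  # amplification of either alone.
  extend <- function(idx_raw, idx_body, endpt) {
    outward <- endpt - rp[idx_raw[1], ]
    d1 <- fit_dir(rp[idx_raw, , drop = FALSE], outward)
    d2 <- fit_dir(body[idx_body, , drop = FALSE], outward)
    dirv <- d1 + d2
    dirv <- dirv / sqrt(sum(dirv^2))
    hit <- ray_polygon_intersection(endpt, dirv, cpts, t_max = 2 * diam)
    if (is.null(hit)) stop("extrapolation escaped contour")
    hit$point
  }
  k1 <- n_fit(rp[1, ]); k2 <- n_fit(rp[m, ])
  kb <- min(k, mb)
  start_pt <- extend(k1:1, kb:1, rp[1, ])
  end_pt <- extend((m - k2 + 1):m, (mb - kb + 1):mb, rp[m, ])
  pts <- rbind(start_pt, body, end_pt)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  s <- arc_length(pts)
  structure(list(points = pts, s_px = s, s_um = s * pixel_size,
                 pixel_size = pixel_size, frame_index = contour$frame_index,
                 oriented = FALSE),
            class = "cell_centerline")
}

#' Assign bottom and tip ends of a centerline
#'
#' The end nearer a user-supplied anchor point becomes the bottom; without
#' an anchor, ends are matched to the previous frame's centerline by
#' nearest-endpoint correspondence. With neither, an explicit choice is
#' required (there is no unsupervised way to tell tip from bottom in a
#' single frame).
#'
#' @param centerline a `cell_centerline`.
#' @param prev previous frame's oriented `cell_centerline`, or NULL.
#' @param anchor c(x, y) bottom anchor in the same coordinate frame, or NULL.
#' @return the centerline, oriented bottom (first point) to tip (last), with
#'   `tip_point` and `bottom_point` fields set.
#' @export
orient_centerline <- function(centerline, prev = NULL, anchor = NULL) {
  pts <- centerline$points
  n <- nrow(pts)
  a <- pts[1, ]; b <- pts[n, ]
  flip <- if (!is.null(anchor)) {
    sum((a - anchor)^2) > sum((b - anchor)^2)
  } else if (!is.null(prev)) {
    pb <- prev$bottom_point; pt <- prev$tip_point
    keep_cost <- sum((a - pb)^2) + sum((b - pt)^2)
    flip_cost <- sum((b - pb)^2) + sum((a - pt)^2)
    if (keep_cost == flip_cost)
      stop("ambiguous centerline orientation against previous frame")
    flip_cost < keep_cost
  } else {
    stop("cannot orient centerline: supply an anchor point or a previous frame")
  }
  if (flip) {
    pts <- pts[n:1, , drop = FALSE]
    s <- arc_length(pts)
    centerline$points <- pts
    centerline$s_px <- s
    centerline$s_um <- s * centerline$pixel_size
  }
  centerline$bottom_point <- centerline$points[1, ]
  centerline$tip_point <- centerline$points[nrow(centerline$points), ]
  centerline$oriented <- TRUE
  centerline
}

#' Smooth a centerline polyline by locally weighted regression
#'
#' Locally quadratic loess of x(s) and y(s) against cumulative arc length.
#' Degree 2 keeps the end tangents of a curved axis unbiased, which a
#' locally linear smoother does not.
#'
#' @param polyline n x 2 matrix.
#' @param frac loess span (fraction of points).
#' @return smoothed n x 2 matrix.
#' @export
smooth_polyline <- function(polyline, frac = 0.2) {
  s <- arc_length(polyline)
  cbind(
    stats::predict(stats::loess(polyline[, 1] ~ s, span = frac, degree = 2,
                                surface = "direct")),
    stats::predict(stats::loess(polyline[, 2] ~ s, span = frac, degree = 2,
                                surface = "direct")))
}

#' Medial ridge of a mask by distance transform
#'
#' Independent route to the medial axis used for cross-validation of the
#' Voronoi skeleton: for every interior pixel the Euclidean distance to the
#' contour polyline is computed, and pixels that are local maxima of that
#' distance (within `tol` of the maximum over their 8-neighborhood) form
#' the ridge of maximal inscribed disks.
#'
#' @param mask a `binary_mask`.
#' @param contour matching [cell_contour()].
#' @param tol plateau tolerance in px (default 0.5, half-pixel).
#' @return m x 2 matrix of ridge pixel centers (x, y).
#' @export
medial_ridge <- function(mask, contour, tol = 0.5) {
  grid <- mask$grid
  nr <- nrow(grid); nc <- ncol(grid)
  idx <- which(grid)
  ys <- (idx - 1) %% nr
  xs <- (idx - 1) %/% nr
  cpts <- contour$points
  d <- cpp_dist_to_polyline(xs, ys, c(cpts[, 1], cpts[1, 1]),
                            c(cpts[, 2], cpts[1, 2]))[, 1]
  dmap <- matrix(-Inf, nr, nc)
  dmap[idx] <- d
  inner <- which(dmap > 1)  # skip the 1-px boundary shell
  ridge <- logical(length(inner))
  for (k in seq_along(inner)) {
    i <- inner[k]
    r <- (i - 1) %% nr + 1
    c <- (i - 1) %/% nr + 1
    if (r == 1 || r == nr || c == 1 || c == nc) next
    nb <- dmap[(r - 1):(r + 1), (c - 1):(c + 1)]
    ridge[k] <- dmap[i] >= max(nb) - tol
  }
  sel <- inner[ridge]
  cbind(((sel - 1) %/% nr), ((sel - 1) %% nr))
}

#' Write centerlines and the tip/bottom table to CSV
#' @param centerlines list of oriented `cell_centerline`s.
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
write_centerlines <- function(centerlines, dir) {
  pts <- do.call(rbind, lapply(centerlines, function(cl)
    data.frame(frame = cl$frame_index, s_index = seq_len(nrow(cl$points)) - 1L,
               x = cl$points[, 1], y = cl$points[, 2], s_um = cl$s_um)))
  tb <- do.call(rbind, lapply(centerlines, function(cl)
    data.frame(frame = cl$frame_index, tip_x = cl$tip_point[1],
               tip_y = cl$tip_point[2], bottom_x = cl$bottom_point[1],
               bottom_y = cl$bottom_point[2], L_um = max(cl$s_um))))
  p1 <- file.path(dir, "centerlines.csv")
  p2 <- file.path(dir, "tip_bottom.csv")
  write.csv(pts, p1, row.names = FALSE)
  write.csv(tb, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
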