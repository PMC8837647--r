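# unroll: base-layer extraction, ordering, and spot assignment.

circle_points <- function(n = 100, r = 50) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = r * cos(th) + 60, y = r * sin(th) + 60)
}

test_that("extract_base_layer handles matrices, tables, CSV paths and downscaling", {
  img <- matrix(0, 10, 12)
  img[cbind(c(2, 3, 7, 9, 10), c(1, 5, 6, 11, 12))] <- 1
  pts <- extract_base_layer(img)
  expect_equal(nrow(pts), 5)
  # pixel frame: x = col - 1, y = row - 1
  expect_true(all(pts[, "x"] == c(0, 4, 5, 10, 11)[order(c(1, 5, 6, 11, 12))]))
  expect_error(extract_base_layer(matrix(0, 5, 5)), class = "rollst_empty_error")

  tab <- cbind(x = c(0, 2, 4), y = c(1, 3, 5))
  expect_equal(extract_base_layer(tab), tab, ignore_attr = TRUE)

  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(10, 20), y = c(30, 40)), csv, row.names = FALSE)
  expect_equal(extract_base_layer(csv)[, "y"], c(30, 40), ignore_attr = TRUE)

  # downscale oracle: coordinates divided by f within rounding
  big <- cbind(x = c(100, 200, 301), y = c(50, 151, 249))
  small <- extract_base_layer(big, downscale = 10)
  expect_true(all(abs(small - big / 10) <= 0.5))
})

test_that("knn_adjacency reports per-point mean kNN distances (hand-checked)", {
  pts <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
  adj <- knn_adjacency(pts, k = 2)
  expect_equal(adj$mean_dist, c(1.5, 1.0, 1.5))
  expect_error(knn_adjacency(pts, k = 3), class = "rollst_spec_error")

  # duplicate points give zero distances but adjacency stays defined
  dup <- rbind(pts, c(0, 0), c(5, 0), c(6, 0), c(7, 0))
  adj2 <- knn_adjacency(dup, k = 2)
  expect_true(any(adj2$nn_dist == 0))
  expect_true(all(is.finite(adj2$mean_dist)))

  # k = 5 graph of a spiral is connected
  sp <- make_spiral(spiral_spec(turns = 2, seed = 2))
  adj3 <- knn_adjacency(sp$points, k = 5)
  g <- igraph::graph_from_edgelist(adj3$edges, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("detect_endpoints finds curve extremes and rejects closed curves", {
  line <- cbind(x = 0:9, y = rep(0, 10))
  ep <- detect_endpoints(line, k = 2)
  expect_setequal(ep, c(1, 10))

  sp <- make_spiral(spiral_spec(turns = 2, seed = 11))
  ep2 <- detect_endpoints(sp$points, k = 5)
  true_ends <- sp$true_order[c(1, length(sp$true_order))]
  expect_setequal(ep2, true_ends)

  expect_error(detect_endpoints(circle_points(100), k = 5),
               class = "rollst_closed_curve")

  # endpoint statistic property: endpoints exceed the median mean-kNN distance
  adj <- knn_adjacency(sp$points, k = 5)
  expect_true(all(adj$mean_dist[ep2] > median(adj$mean_dist)))
})

test_that("order_base_layer recovers the generation order up to reversal", {
  set.seed(1)
  line <- cbind(x = sample(0:19), y = 0)
  bl <- suppressMessages(order_base_layer(line, k = 2))
  xs <- bl$points[, "x"]
  expect_true(all(diff(xs) > 0) || all(diff(xs) < 0))
  # the geodesic may skip next-to-endpoint points; ends are always kept
  expect_gte(nrow(bl$points), 18)
  expect_setequal(xs[c(1, length(xs))], c(0, 19))

  # spiral: path vertices strictly monotone in the true order
  sp <- make_spiral(spiral_spec(turns = 2, seed = 3))
  bl2 <- suppressMessages(order_base_layer(sp$points, k = 5))
  true_pos <- order(sp$true_order)[bl2$order]  # rank along the true curve
  expect_true(all(diff(true_pos) > 0) || all(diff(true_pos) < 0))

  # disconnected segments
  seg <- rbind(cbind(x = 0:9, y = 0), cbind(x = 0:9, y = 1000))
  expect_error(order_base_layer(seg, endpoints = c(1, 20), k = 2),
               class = "rollst_disconnected")
})

test_that("tangents follow the curve direction", {
  line <- cbind(x = 0:29, y = rep(5, 30))
  bl <- order_base_layer(line, k = 2)
  tg <- tangents(bl, window = 5)
  expect_true(all(abs(abs(tg[, 1]) - 1) < 1e-12) && all(tg[, 2] == 0))
  # endpoints fall back to one-sided differences
  expect_equal(tangent_at(bl, 1), tg[1, ])

  # circle arc: tangent perpendicular to radius within 2 degrees
  th <- seq(0, pi, length.out = 200)
  arcp <- cbind(x = 100 * cos(th), y = 100 * sin(th))
  bla <- structure(list(points = arcp, order = seq_len(200),
                        endpoints = c(1, 200), n_dropped = 0),
                   class = "base_layer")
  tga <- tangents(bla, window = 5)
  inner <- 10:190
  dots <- abs(rowSums(tga[inner, ] * arcp[inner, ] / 100))
  expect_lt(max(dots), sin(2 * pi / 180))
})

test_that("assign_spots applies radius and angle gates and keeps min-distance pairs", {
  base_pts <- cbind(x = 0:49, y = rep(0, 50))
  bl <- suppressMessages(order_base_layer(base_pts, k = 2))
  # order may be reversed; normalize to ascending x for index arithmetic
  if (bl$points[1, "x"] > bl$points[2, "x"]) {
    bl$points <- bl$points[rev(seq_len(nrow(bl$points))), ]
    bl$order <- rev(bl$order)
  }

  spots <- rbind(
    perp = c(7, 10),      # perpendicular above base point with x = 7
    far = c(25, 100.5),   # beyond the 80 px radius of every base point
    shallow = c(40 + 30 * cos(20 * pi / 180), 30 * sin(20 * pi / 180))
  )
  uc <- assign_spots(bl, spots, radius = 80)
  expect_equal(uc$x[1], which(bl$points[, "x"] == 7) - 1)
  expect_equal(uc$y[1], 10)
  expect_false(uc$assigned[2])   # radius gate
  expect_false(uc$assigned[3])   # 20 degrees to the tangent: angle gate

  # a spot within reach of two base points keeps the closer one only
  two <- cbind(x = c(0, 21), y = c(0, 0))
  blt <- order_base_layer(two, endpoints = c(1, 2), k = 1)
  spot <- cbind(12, 9)  # distances 15 and ~12.7 -> nearer point wins
  uct <- assign_spots(blt, spot, radius = 80, angle_min = 0, angle_max = 180)
  expect_equal(uct$matched_point, which.min(sqrt(colSums((t(blt$points) - c(12, 9))^2))))
  expect_equal(uct$y, min(sqrt(rowSums(sweep(blt$points, 2, c(12, 9))^2))))
})

test_that("unroll_pipeline recovers arc and depth on the synthetic spiral", {
  sim <- default_sim()
  uc <- suppressMessages(unroll_pipeline(sim$ds, sim$truth$base_points))
  s <- attr(uc, "summary")
  expect_gte(s$n_assigned / s$n_spots, 0.95)
  ok <- uc$assigned
  rho <- cor(uc$x[ok], sim$truth$arc_length[ok], method = "spearman")
  expect_gte(abs(rho), 0.99)

  # determinism
  uc2 <- suppressMessages(unroll_pipeline(sim$ds, sim$truth$base_points))
  expect_identical(as.data.frame(uc), as.data.frame(uc2))

  # radius 0 assigns nothing
  uc0 <- suppressMessages(unroll_pipeline(sim$ds, sim$truth$base_points, radius = 0))
  expect_equal(sum(uc0$assigned), 0)
})

test_that("unrolling is invariant to mirroring up to global order reversal", {
  sim <- default_sim()
  spots <- sim$ds$pixel_xy
  pts <- sim$truth$base_points
  uc <- suppressMessages(unroll_pipeline(spots, pts))
  mir_spots <- spots; mir_spots[, 1] <- -mir_spots[, 1]
  mir_pts <- pts; mir_pts[, 1] <- -mir_pts[, 1]
  ucm <- suppressMessages(unroll_pipeline(mir_spots, mir_pts))
  expect_equal(ucm$y, uc$y, tolerance = 1e-9)
  xmax <- max(uc$x, na.rm = TRUE)
  same <- identical(ucm$x, uc$x)
  reversed <- isTRUE(all.equal(ucm$x, xmax - uc$x))
  expect_true(same || reversed)
})
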