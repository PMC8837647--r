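# Digital unrolling: order a traced base-layer curve endpoint to endpoint
# via a kNN-graph geodesic and project spots into a linear
# (proximal-distal x serosa-luminal) coordinate system.

#' Extract base-layer points from a mask
#'
#' Accepts a binary matrix (nonzero = curve), a two-column pixel table, a
#' CSV path with columns x,y, or a PNG path (read via the `png` package;
#' any nonzero channel marks a curve pixel). Matrix/PNG pixels are mapped
#' to the shared pixel frame: x = column index - 1, y = row index - 1
#' (origin top-left, y downward, 0-based).
#'
#' @param mask matrix, data.frame, or file path
#' @param downscale optional downscale factor f > 1: coordinates divided by
#'   f and rounded, duplicates collapsed
#' @return n x 2 matrix with columns `x`, `y`
#' @export
extract_base_layer <- function(mask, downscale = 1) {
  if (is.character(mask)) {
    if (grepl("\\.png$", mask, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) {
        rollst_stop("rollst_io_error", "reading PNG masks requires the 'png' package")
      }
      img <- png::readPNG(mask)
      if (length(dim(img)) == 3) img <- img[, , 1]
      mask <- img
    } else {
      df <- read.csv(mask)
      mask <- as.matrix(df[, 1:2])
    }
  }
  if (is.data.frame(mask)) mask <- as.matrix(mask[, 1:2])
  is_points <- ncol(mask) == 2 && !is.null(colnames(mask)) &&
    all(c("x", "y") %in% colnames(mask))
  if (is_points) {
    pts <- mask[, c("x", "y"), drop = FALSE]
  } else {
    # binary image matrix: rows are y (downward), columns are x
    idx <- which(mask != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) rollst_stop("rollst_empty_error", "mask has no nonzero pixels")
    pts <- cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
  }
  if (nrow(pts) == 0) rollst_stop("rollst_empty_error", "mask has no points")
  if (downscale != 1) {
    pts <- round(pts / downscale)
    pts <- unique(pts)
  }
  storage.mode(pts) <- "double"
  pts
}

#' k-nearest-neighbour adjacency of a point set
#'
#' kd-tree kNN search; the adjacency is symmetrized (undirected).
#'
#' @param points n x 2 matrix
#' @param k neighbours per point (default 5)
#' @return list with `edges` (m x 2 matrix of point indices, i < j),
#'   `mean_dist` (per-point mean distance to its k nearest neighbours) and
#'   `nn_index` / `nn_dist` (n x k matrices)
#' @export
knn_adjacency <- function(points, k = 5) {
  n <- nrow(points)
  if (n < k + 1) {
    rollst_stop("rollst_spec_error", "need at least k+1 = %d points, got %d",
                k + 1, n)
  }
  nn <- FNN::get.knn(points, k = k)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$nn.index)
  e <- cbind(pmin(from, to), pmax(from, to))
  e <- unique(e)
  list(edges = e,
       mean_dist = rowMeans(nn$nn.dist),
       nn_index = nn$nn.index,
       nn_dist = nn$nn.dist)
}

#' Detect the endpoints of an open curve
#'
#' On a uniformly sampled open curve, the two endpoints have one-sided
#' neighbourhoods and therefore an extremal mean distance to their k nearest
#' neighbours (largest, in the default mode; a `"smallest"` switch is
#' provided). A curve whose extremal statistic is not separated from the
#' bulk (robust z-score below `z_min`) has no endpoints and raises a
#' closed-curve error.
#'
#' @param points n x 2 matrix
#' @param k neighbours (default 5)
#' @param mode `"largest"` (geometric default) or `"smallest"`
#' @param z_min required robust z-score separation of the endpoint
#'   statistic from the bulk (default 2)
#' @param adj optional precomputed [knn_adjacency()]
#' @return integer vector of two point indices, ordered by decreasing
#'   statistic extremity then by index
#' @export
detect_endpoints <- function(points, k = 5, mode = c("largest", "smallest"),
                             z_min = 2, adj = NULL) {
  mode <- match.arg(mode)
  if (is.null(adj)) adj <- knn_adjacency(points, k)
  stat <- adj$mean_dist
  if (mode == "smallest") stat <- -stat
  ord <- order(-stat, seq_along(stat))
  ep <- ord[1:2]
  if (diff(range(stat)) <= 1e-9 * max(abs(median(stat)), 1e-12)) {
    rollst_stop("rollst_closed_curve",
                "mean kNN distance is uniform: curve appears closed")
  }
  scale <- stats::mad(stat)
  if (scale == 0) scale <- sd(stat)
  z <- if (scale > 0) (stat[ep] - median(stat)) / scale else rep(0, 2)
  if (!all(is.finite(z)) || any(z < z_min)) {
    rollst_stop("rollst_closed_curve",
                "no endpoint signature (z = %.2f, %.2f < %g): curve appears closed",
                z[1], z[2], z_min)
  }
  ep
}

#' Order base-layer points from endpoint to endpoint
#'
#' Builds the undirected kNN graph and extracts the shortest path (minimum
#' vertex count, unweighted) between the two endpoints. Points off the path
#' are dropped (with a message); the retained, ordered subset is the base
#' layer every downstream coordinate refers to.
#'
#' @param points n x 2 matrix
#' @param endpoints pair of point indices; detected if `NULL`
#' @param k neighbours (default 5)
#' @param ... passed to [detect_endpoints()]
#' @return object of class `base_layer`: list with `points` (ordered m x 2
#'   matrix), `order` (indices into the input point set), `endpoints`,
#'   `n_dropped`
#' @export
order_base_layer <- function(points, endpoints = NULL, k = 5, ...) {
  adj <- knn_adjacency(points, k)
  if (is.null(endpoints)) endpoints <- detect_endpoints(points, k, adj = adj, ...)
  g <- igraph::graph_from_edgelist(adj$edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < nrow(points)) {
    g <- igraph::add_vertices(g, nrow(points) - igraph::vcount(g))
  }
  comp <- igraph::components(g)$membership
  if (comp[endpoints[1]] != comp[endpoints[2]]) {
    rollst_stop("rollst_disconnected",
                "endpoints lie in different kNN-graph components; try a larger k")
  }
  path <- igraph::shortest_paths(g, from = endpoints[1], to = endpoints[2],
                                 output = "vpath")$vpath[[1]]
  ord <- as.integer(path)
  dropped <- nrow(points) - length(ord)
  if (dropped > 0) {
    message(sprintf("order_base_layer: %d point(s) off the geodesic dropped", dropped))
  }
  structure(list(points = points[ord, , drop = FALSE],
                 order = ord,
                 endpoints = endpoints,
                 n_dropped = dropped),
            class = "base_layer")
}

#' @export
print.base_layer <- function(x, ...) {
  cat(sprintf("base_layer: %d ordered points (%d dropped), endpoints %d -> %d\n",
              nrow(x$points), x$n_dropped, x$endpoints[1], x$endpoints[2]))
  invisible(x)
}

#' Tangent directions along an ordered base layer
#'
#' Central difference between order-neighbours `i - window` and
#' `i + window`, clamped at the curve ends (one-sided difference there);
#' unit norm. The tangent points toward increasing order index.
#'
#' @param base a [order_base_layer()] result
#' @param window half-window in ordered points (default 5)
#' @return m x 2 matrix of unit tangents
#' @export
tangents <- function(base, window = 5) {
  p <- base$points
  m <- nrow(p)
  lo <- pmax(seq_len(m) - window, 1)
  hi <- pmin(seq_len(m) + window, m)
  d <- p[hi, , drop = FALSE] - p[lo, , drop = FALSE]
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  d / nrm
}

#' Tangent at a single base-layer point
#' @param base a [order_base_layer()] result
#' @param i order index (1-based)
#' @param window half-window (default 5)
#' @return unit 2-vector
#' @export
tangent_at <- function(base, i, window = 5) {
  tangents(base, window)[i, ]
}

#' Assign spots to base-layer points (the unrolling step)
#'
#' For every base point, candidate spots are those within `radius` whose
#' undirected angle between the local tangent direction and the
#' base-to-spot vector (taken in `[0, 180]` degrees) lies in
#' `[angle_min, angle_max]`. Among all candidate (base point, spot) pairs,
#' each spot keeps only its minimum-distance pair (ties: lower base-point
#' order index). Assigned spots get `x` = 0-based order index of the kept
#' base point and `y` = that Euclidean distance; spots with no admissible
#' pair are flagged unassigned, never fatal.
#'
#' @param base a [order_base_layer()] result
#' @param spots n x 2 matrix of spot pixel coordinates
#' @param spot_ids optional ids (default rownames or 1..n)
#' @param radius search radius, px (default 80)
#' @param angle_min,angle_max tangent-angle window, degrees (default 35-125,
#'   kept asymmetric as configured)
#' @param tangent_window half-window for tangent estimation
#' @return data.frame of class `unrolled_coords`: columns `spot_id`, `x`,
#'   `y`, `matched_point` (1-based order index, NA if unassigned),
#'   `assigned`
#' @export
assign_spots <- function(base, spots, spot_ids = NULL, radius = 80,
                         angle_min = 35, angle_max = 125,
                         tangent_window = 5) {
  p <- base$points
  m <- nrow(p)
  n <- nrow(spots)
  if (is.null(spot_ids)) spot_ids <- rownames(spots) %||% as.character(seq_len(n))
  tg <- tangents(base, tangent_window)

  best_d <- rep(Inf, n)
  best_j <- rep(NA_integer_, n)
  # distances spot x base computed in column blocks to bound memory
  block <- max(1L, floor(2e6 / n))
  cosmin <- cos(angle_max * pi / 180)  # angle <= angle_max  <=> cos >= cosmin
  cosmax <- cos(angle_min * pi / 180)  # angle >= angle_min  <=> cos <= cosmax
  for (start in seq(1L, m, by = block)) {
    jj <- start:min(start + block - 1L, m)
    dx <- outer(spots[, 1], p[jj, 1], "-")
    dy <- outer(spots[, 2], p[jj, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    dsafe <- pmax(d, .Machine$double.eps)
    ct <- (dx * rep(tg[jj, 1], each = n) + dy * rep(tg[jj, 2], each = n)) / dsafe
    ok <- d <= radius & ct >= cosmin & ct <= cosmax
    d[!ok] <- Inf
    jmin <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_len(n), jmin)]
    upd <- dmin < best_d
    best_d[upd] <- dmin[upd]
    best_j[upd] <- jj[jmin[upd]]
  }
  assigned <- is.finite(best_d)
  res <- data.frame(spot_id = spot_ids,
                    x = ifelse(assigned, best_j - 1L, NA_integer_),
                    y = ifelse(assigned, best_d, NA_real_),
                    matched_point = ifelse(assigned, best_j, NA_integer_),
                    assigned = assigned,
                    stringsAsFactors = FALSE)
  class(res) <- c("unrolled_coords", "data.frame")
  res
}

#' Run the full digital-unrolling pipeline
#'
#' extract -> kNN -> endpoints -> order -> assign. The returned coordinates
#' carry a `summary` attribute (counts, endpoint coordinates, drop counts).
#'
#' @param ds a [spatial_dataset()] (its `pixel_xy` are the spots), or an
#'   n x 2 coordinate matrix
#' @param mask anything [extract_base_layer()] accepts
#' @param k kNN neighbours (default 5)
#' @param radius,angle_min,angle_max see [assign_spots()]
#' @param downscale mask downscale factor
#' @param endpoint_mode see [detect_endpoints()]
#' @param tangent_window see [tangents()]
#' @return an `unrolled_coords` data.frame
#' @export
unroll_pipeline <- function(ds, mask, k = 5, radius = 80, angle_min = 35,
                            angle_max = 125, downscale = 1,
                            endpoint_mode = "largest", tangent_window = 5) {
  if (inherits(ds, "spatial_dataset")) {
    spots <- ds$pixel_xy
    rownames(spots) <- ds$spot_ids
  } else {
    spots <- as.matrix(ds)
  }
  pts <- extract_base_layer(mask, downscale = downscale)
  base <- order_base_layer(pts, k = k, mode = endpoint_mode)
  uc <- assign_spots(base, spots, radius = radius, angle_min = angle_min,
                     angle_max = angle_max, tangent_window = tangent_window)
  attr(uc, "summary") <- list(
    n_spots = nrow(uc),
    n_assigned = sum(uc$assigned),
    n_base_points = nrow(base$points),
    n_base_dropped = base$n_dropped,
    endpoint_xy = base$points[c(1, nrow(base$points)), , drop = FALSE]
  )
  attr(uc, "base_layer") <- base
  uc
}
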