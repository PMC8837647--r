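# Synthetic Swiss-roll generator: Archimedean-spiral tissue with a layered
# spot lattice, planted spatial programs, planted pathway footprints and
# negative-binomial counts. Everything is seeded and returned alongside its
# ground truth so downstream stages can be validated exactly.

#' Specification of a synthetic Swiss roll
#'
#' The rolled tissue is modelled as an Archimedean spiral `r = a + b*theta`
#' (closed forms for tangent and normal). Spots sit at fixed radial offsets
#' ("depths") inward from the base layer, emulating muscle, lamina propria
#' and epithelium layers.
#'
#' @param a inner radius, px
#' @param b radial growth per radian, px/rad; the winding gap is `2*pi*b`
#' @param turns number of full turns (>= 1)
#' @param point_step arc-length spacing of base-layer points, px
#' @param spot_step arc-length spacing of the spot lattice, px
#' @param depths radial offsets (px) of the spot layers, inward from the
#'   base layer; each must be smaller than half the winding gap so that no
#'   spot lies closer to the neighbouring winding than to its own
#' @param jitter positional jitter applied to spots, px (<= spot_step / 4)
#' @param seed RNG seed driving the point shuffle, jitter and counts
#' @return object of class `spiral_spec`
#' @export
spiral_spec <- function(a = 60, b = 16, turns = 3, point_step = 2,
                        spot_step = 4, depths = c(10, 25, 40),
                        jitter = spot_step / 4, seed = 1L) {
  if (a <= 0 || b <= 0) rollst_stop("rollst_spec_error", "a and b must be > 0")
  if (turns < 1) rollst_stop("rollst_spec_error", "turns must be >= 1")
  if (any(depths <= 0)) rollst_stop("rollst_spec_error", "depths must be > 0")
  if (2 * pi * b <= max(depths)) {
    rollst_stop("rollst_spec_error",
                "overlapping windings: winding gap 2*pi*b = %.1f <= max depth %.1f",
                2 * pi * b, max(depths))
  }
  if (jitter > spot_step / 4 + 1e-9) {
    rollst_stop("rollst_spec_error", "jitter must be <= spot_step / 4")
  }
  structure(list(a = a, b = b, turns = turns, point_step = point_step,
                 spot_step = spot_step, depths = depths, jitter = jitter,
                 seed = as.integer(seed)),
            class = "spiral_spec")
}

# Dense theta grid with cumulative arc length; shared by make_spiral and
# place_spots so both sample the identical curve.
spiral_grid <- function(spec, n = 20000L) {
  theta <- seq(0, 2 * pi * spec$turns, length.out = n)
  r <- spec$a + spec$b * theta
  ds <- sqrt(r^2 + spec$b^2)                 # |d(position)/d(theta)|
  arc <- c(0, cumsum((ds[-1] + ds[-n]) / 2 * diff(theta)))
  list(theta = theta, arc = arc, total = arc[n])
}

# Point, unit tangent and inward unit normal at arc positions s.
spiral_eval <- function(spec, s, grid = spiral_grid(spec)) {
  theta <- approx(grid$arc, grid$theta, xout = s, rule = 2)$y
  r <- spec$a + spec$b * theta
  cx <- spec$a + spec$b * 2 * pi * spec$turns + max(spec$depths) + 20
  x <- cx + r * cos(theta)
  y <- cx + r * sin(theta)
  dx <- spec$b * cos(theta) - r * sin(theta)
  dy <- spec$b * sin(theta) + r * cos(theta)
  nrm <- sqrt(dx^2 + dy^2)
  tx <- dx / nrm; ty <- dy / nrm
  # inward normal: rotate tangent, pick the side facing the spiral centre
  nx <- -ty; ny <- tx
  outward <- (nx * (cx - x) + ny * (cx - y)) < 0
  nx[outward] <- -nx[outward]; ny[outward] <- -ny[outward]
  list(x = x, y = y, tx = tx, ty = ty, nx = nx, ny = ny, theta = theta)
}

#' Sample the base-layer curve of a synthetic Swiss roll
#'
#' Points are placed on the spiral at approximately `point_step` arc spacing
#' and returned in shuffled order (as a traced mask would be), with the true
#' ordering retained as ground truth.
#'
#' @param spec a [spiral_spec()]
#' @return list with `points` (shuffled n x 2 matrix, columns x/y),
#'   `true_order` (integer permutation: `points[true_order, ]` walks the
#'   curve from the inner to the outer end), `arc_length` (per shuffled
#'   point) and `total_arc`
#' @export
make_spiral <- function(spec) {
  stopifnot(inherits(spec, "spiral_spec"))
  grid <- spiral_grid(spec)
  s <- seq(0, grid$total, by = spec$point_step)
  ev <- spiral_eval(spec, s, grid)
  pts <- cbind(x = ev$x, y = ev$y)
  set.seed(spec$seed)
  perm <- sample.int(nrow(pts))
  list(points = pts[perm, , drop = FALSE],
       true_order = order(perm),
       arc_length = s[perm],
       total_arc = grid$total)
}

#' Place the layered spot lattice of a synthetic Swiss roll
#'
#' Spots are laid at each configured depth along the inward normal of the
#' spiral, spaced `spot_step` in arc length, with uniform jitter of at most
#' `spot_step / 4` in each axis.
#'
#' @param spec a [spiral_spec()]
#' @param round_px round spot coordinates to integer pixels (the Visium
#'   positions dialect stores integers)
#' @return list with `xy` (n x 2 matrix), `arc_length` and `depth` (per-spot
#'   ground truth, pre-jitter), `spot_ids`
#' @export
place_spots <- function(spec, round_px = TRUE) {
  stopifnot(inherits(spec, "spiral_spec"))
  grid <- spiral_grid(spec)
  s <- seq(spec$spot_step, grid$total - spec$spot_step, by = spec$spot_step)
  ev <- spiral_eval(spec, s, grid)
  n_per_layer <- length(s)
  xs <- ys <- arcs <- deps <- NULL
  for (d in spec$depths) {
    xs <- c(xs, ev$x + d * ev$nx)
    ys <- c(ys, ev$y + d * ev$ny)
    arcs <- c(arcs, s)
    deps <- c(deps, rep(d, n_per_layer))
  }
  set.seed(spec$seed + 1L)
  if (spec$jitter > 0) {
    xs <- xs + runif(length(xs), -spec$jitter, spec$jitter)
    ys <- ys + runif(length(ys), -spec$jitter, spec$jitter)
  }
  if (round_px) { xs <- round(xs); ys <- round(ys) }
  list(xy = cbind(x = xs, y = ys),
       arc_length = arcs, depth = deps,
       spot_ids = sprintf("S%05d-1", seq_along(xs)))
}

#' Soft indicator of an interval
#'
#' Product of two logistic ramps: ~1 inside `[lo, hi]`, ~0 outside, with a
#' soft transition of width ~`4 * scale`. The building block for planted
#' program regions.
#'
#' @param v positions (arc length or depth, px)
#' @param lo,hi interval bounds, px
#' @param scale logistic s-parameter, px
#' @return values in `(0, 1)`
#' @export
logistic_band <- function(v, lo, hi, scale) {
  plogis((v - lo) / scale) * plogis((hi - v) / scale)
}

#' Default planted-program layout
#'
#' Seven programs over the (arc, depth) plane: three depth layers (muscle,
#' lamina propria, epithelium split into proximal and distal halves),
#' follicle hotspots at isolated arc positions, stem-cell hotspots in the
#' distal epithelium, and a p53-footprint activity constructed as
#' `1 - stem / max(stem)` so that corr(stem, p53) = -1 by construction.
#' Region edges are soft (logistic falloff, scale `2 * spot_step`).
#'
#' @param spec a [spiral_spec()]
#' @param total_arc total arc length of the curve, px
#' @return list of per-factor descriptors consumed by [plant_programs()]
#' @export
default_layout <- function(spec, total_arc) {
  # soft edges: logistic transition of total width ~ 2 * spot_step
  # (logistic s-parameter = width / 4, the 10-90% span of plogis)
  sc <- spec$spot_step / 2
  dd <- spec$depths
  half <- min(diff(sort(dd))) / 2 - 1
  S <- total_arc
  band <- function(center) function(s, d) logistic_band(d, center - half, center + half, sc)
  hotspots <- function(centers, width, depth_center) function(s, d) {
    bump <- rowSums(sapply(centers, function(c0)
      logistic_band(s, c0 - width, c0 + width, sc)))
    pmin(bump, 1) * logistic_band(d, depth_center - half, depth_center + half, sc)
  }
  list(
    muscle    = list(fun = band(dd[1]), markers = 10, amplitude = 1,
                     marker_prefix = "mus"),
    lp        = list(fun = band(dd[2]), markers = 10, amplitude = 1,
                     marker_prefix = "lp"),
    epi_prox  = list(fun = function(s, d) band(dd[3])(s, d) * plogis((0.5 * S - s) / sc),
                     markers = 10, amplitude = 1, marker_prefix = "pep"),
    epi_dist  = list(fun = function(s, d) band(dd[3])(s, d) * plogis((s - 0.5 * S) / sc),
                     markers = 10, amplitude = 1, marker_prefix = "dep"),
    follicle  = list(fun = hotspots(S * c(0.15, 0.45, 0.75), 30, dd[2]),
                     markers = 10, amplitude = 1, marker_prefix = "fol"),
    stem      = list(fun = hotspots(S * c(0.55, 0.65, 0.75, 0.85, 0.95), 70, dd[3]),
                     markers = 25, amplitude = 1.5, marker_prefix = "stem")
  )
}

#' Plant spatial transcriptional programs
#'
#' Builds the ground-truth activity matrix `true_W` (one column per planted
#' program, plus the anti-correlated p53-footprint activity) and loading
#' matrix `true_H`. Each program gets exclusive high-loading marker genes;
#' pathway footprint genes are loaded on the activity that drives them
#' (TNFa-like and NFkB-like on the distal damage program, Wnt-like on the
#' lamina-propria program, p53 on its own inverted-stem activity); every
#' gene additionally carries a shared low-level background loading.
#'
#' @param arc_length,depth per-spot ground-truth coordinates from
#'   [place_spots()]
#' @param n_genes total number of genes (>= 250 to fit all planted sets)
#' @param layout list of program descriptors, see [default_layout()]
#' @param use_stem_symbols name the stem markers with the packaged 25-gene
#'   proliferating stem-cell signature symbols ([stem_signature()])
#' @param marker_loading,footprint_loading,background_loading loading levels
#'   in `true_H`
#' @param n_dispersed number of background genes flagged as high-dispersion
#'   (overdispersed but spatially unstructured - the noise-variable genes
#'   that dominate real variable-feature sets)
#' @return list with `true_W` (spots x factors), `true_H` (factors x
#'   genes), `p53_activity` / `p53_H` (the planted anti-correlated
#'   footprint activity and its gene loadings, kept out of the factor
#'   matrices: the planted NNMF rank is `ncol(true_W)`), `planted_sets`
#'   (named gene sets), `factor_genes` (per factor, all genes with elevated
#'   planted loading), `pathway_model` (data.frame pathway/gene/weight)
#' @export
plant_programs <- function(arc_length, depth, n_genes = 1200,
                           layout, use_stem_symbols = TRUE,
                           marker_loading = 3, footprint_loading = 1.5,
                           background_loading = 0.02, n_dispersed = 300) {
  n_fp <- 30L
  n_markers <- sum(vapply(layout, function(l) as.integer(l$markers), 1L))
  n_special <- n_markers + 4L * n_fp
  if (n_genes < n_special + 50) {
    rollst_stop("rollst_spec_error", "n_genes too small for planted sets (need > %d)",
                n_special + 50)
  }
  genes <- character(0)
  planted_sets <- list()
  for (nm in names(layout)) {
    l <- layout[[nm]]
    mk <- if (nm == "stem" && use_stem_symbols) {
      stem_signature()[seq_len(l$markers)]
    } else sprintf("%s%02d", l$marker_prefix, seq_len(l$markers))
    planted_sets[[nm]] <- mk
    genes <- c(genes, mk)
  }
  fp_names <- list(p53 = sprintf("p53fp%02d", 1:n_fp),
                   tnfa = sprintf("tnfafp%02d", 1:n_fp),
                   nfkb = sprintf("nfkbfp%02d", 1:n_fp),
                   wnt = sprintf("wntfp%02d", 1:n_fp))
  for (nm in names(fp_names)) {
    planted_sets[[paste0(nm, "_footprint")]] <- fp_names[[nm]]
    genes <- c(genes, fp_names[[nm]])
  }
  n_bg <- n_genes - length(genes)
  if (n_dispersed >= n_bg) {
    rollst_stop("rollst_spec_error", "n_dispersed must be < %d background genes", n_bg)
  }
  dispersed <- sprintf("hv%04d", seq_len(n_dispersed))
  genes <- c(genes, dispersed, sprintf("bg%04d", seq_len(n_bg - n_dispersed)))

  W <- sapply(layout, function(l) l$amplitude * l$fun(arc_length, depth))
  rownames(W) <- NULL
  # planted p53-footprint activity: inverted stem activity, so
  # corr(stem, p53) = -1 by construction; a footprint activity, not an
  # NNMF factor (the planted rank is ncol(true_W)). Layouts without a
  # stem program get a flat p53 activity.
  p53 <- if ("stem" %in% colnames(W)) {
    1 - W[, "stem"] / max(W[, "stem"])
  } else rep(1, nrow(W))

  H <- matrix(background_loading, nrow = ncol(W), ncol = length(genes),
              dimnames = list(colnames(W), genes))
  for (nm in names(layout)) H[nm, planted_sets[[nm]]] <- marker_loading
  # footprint genes ride on the activity of a driving program when present
  if ("epi_dist" %in% rownames(H)) {
    H["epi_dist", fp_names$tnfa] <- footprint_loading
    H["epi_dist", fp_names$nfkb] <- footprint_loading
  }
  if ("lp" %in% rownames(H)) H["lp", fp_names$wnt] <- footprint_loading
  H_p53 <- matrix(background_loading, 1, length(genes),
                  dimnames = list("p53", genes))
  H_p53[1, fp_names$p53] <- footprint_loading

  # per factor, every gene with an elevated planted loading (exclusive
  # markers plus the footprint genes riding on that factor's activity)
  factor_genes <- lapply(colnames(W), function(nm)
    colnames(H)[H[nm, ] > background_loading])
  names(factor_genes) <- colnames(W)

  pm <- do.call(rbind, lapply(names(fp_names), function(nm)
    data.frame(pathway = nm, gene = fp_names[[nm]], weight = 1,
               stringsAsFactors = FALSE)))
  list(true_W = W, true_H = H, p53_activity = p53, p53_H = H_p53,
       planted_sets = planted_sets, factor_genes = factor_genes,
       dispersed_genes = dispersed, pathway_model = pm)
}

#' Sample negative-binomial counts from planted programs
#'
#' `counts[s, g] ~ NB(mean = size_s * (W H)[s, g] + baseline, size = theta)`.
#' As `theta -> Inf` the distribution collapses to Poisson.
#'
#' @param true_W spot x factor activity matrix
#' @param true_H factor x gene loading matrix
#' @param size_factors per-spot size factor (default log-normal around 1)
#' @param theta NB size (inverse overdispersion), default 10; scalar or
#'   one value per gene
#' @param baseline mean added to every gene so no gene is identically zero
#' @param seed RNG seed
#' @return integer matrix spots x genes (dense)
#' @export
sample_counts <- function(true_W, true_H, size_factors = NULL, theta = 10,
                          baseline = 0.2, seed = 1L) {
  set.seed(seed)
  n_s <- nrow(true_W)
  if (is.null(size_factors)) size_factors <- rlnorm(n_s, 0, 0.15)
  mu <- size_factors * (true_W %*% true_H + baseline)
  size <- if (length(theta) == ncol(mu)) rep(theta, each = n_s) else theta
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                   nrow = n_s, dimnames = dimnames(mu))
  counts
}

#' Simulate a complete synthetic Swiss-roll dataset
#'
#' Composition of [make_spiral()], [place_spots()], [plant_programs()] and
#' [sample_counts()]; fully deterministic given `spec$seed`.
#'
#' @param spec a [spiral_spec()]
#' @param n_genes number of genes
#' @param theta NB size parameter for regular genes
#' @param dispersed_theta NB size for the high-dispersion unstructured
#'   background genes (see [plant_programs()])
#' @param baseline baseline mean expression
#' @param layout planted-program layout; default [default_layout()]
#' @param sample sample label
#' @return list with `ds` (a [spatial_dataset()]) and `truth` (list:
#'   `base_points` shuffled base-layer points, `true_order`, `base_arc`,
#'   `arc_length`/`depth` per spot, `true_W`, `true_H`, `planted_sets`,
#'   `pathway_model`, `total_arc`)
#' @export
simulate_swissroll <- function(spec = spiral_spec(), n_genes = 1200,
                               theta = 10, dispersed_theta = 1,
                               baseline = 0.2, layout = NULL,
                               sample = "sim") {
  spiral <- make_spiral(spec)
  spots <- place_spots(spec)
  if (is.null(layout)) layout <- default_layout(spec, spiral$total_arc)
  prog <- plant_programs(spots$arc_length, spots$depth, n_genes, layout)
  gene_theta <- setNames(rep(theta, ncol(prog$true_H)), colnames(prog$true_H))
  gene_theta[prog$dispersed_genes] <- dispersed_theta
  counts <- sample_counts(cbind(prog$true_W, p53 = prog$p53_activity),
                          rbind(prog$true_H, prog$p53_H), theta = gene_theta,
                          baseline = baseline, seed = spec$seed + 2L)
  biotypes <- setNames(rep("protein_coding", ncol(counts)), colnames(counts))
  ds <- spatial_dataset(counts, colnames(counts), spots$spot_ids,
                        spots$xy, sample = sample, gene_biotypes = biotypes)
  rownames(prog$true_W) <- spots$spot_ids
  list(ds = ds,
       truth = list(base_points = spiral$points,
                    true_order = spiral$true_order,
                    base_arc = spiral$arc_length,
                    total_arc = spiral$total_arc,
                    arc_length = spots$arc_length,
                    depth = spots$depth,
                    true_W = prog$true_W,
                    true_H = prog$true_H,
                    p53_activity = prog$p53_activity,
                    factor_genes = prog$factor_genes,
                    dispersed_genes = prog$dispersed_genes,
                    planted_sets = prog$planted_sets,
                    pathway_model = prog$pathway_model,
                    spec = spec))
}

#' Write a simulated dataset to disk in 10x-style layout
#'
#' Emits `matrix.mtx` (genes x spots), `features.tsv`, `barcodes.tsv`,
#' `tissue_positions.csv` (Visium dialect, header included), the base-layer
#' mask as a two-column pixel CSV (`mask.csv`), the planted pathway model
#' (`pathway_model.csv`), planted gene sets (`planted_sets.gmt`) and
#' ground-truth tables. Everything is plain text and readable back with
#' [read_spatial()] / [extract_base_layer()] / [read_pathway_model()] /
#' [read_gmt()].
#'
#' @param sim output of [simulate_swissroll()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
emit_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$ds
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  feats <- data.frame(id = ds$gene_ids, symbol = ds$gene_ids,
                      type = "Gene Expression",
                      biotype = unname(ds$gene_biotypes[ds$gene_ids]))
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  pos <- data.frame(barcode = ds$spot_ids, in_tissue = 1L,
                    array_row = 0L, array_col = 0L,
                    pxl_row_in_fullres = as.integer(ds$pixel_xy[, "y"]),
                    pxl_col_in_fullres = as.integer(ds$pixel_xy[, "x"]))
  write.csv(pos, file.path(dir, "tissue_positions.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(x = sim$truth$base_points[, "x"],
                       y = sim$truth$base_points[, "y"]),
            file.path(dir, "mask.csv"), row.names = FALSE, quote = FALSE)
  write.csv(sim$truth$pathway_model, file.path(dir, "pathway_model.csv"),
            row.names = FALSE, quote = FALSE)
  write_gmt(sim$truth$planted_sets, file.path(dir, "planted_sets.gmt"))
  write_table(data.frame(spot_id = ds$spot_ids,
                         arc_length = sim$truth$arc_length,
                         depth = sim$truth$depth),
              file.path(dir, "truth_spots.tsv"))
  write_table(sim$truth$true_W, file.path(dir, "truth_W.tsv"),
              id_col = "spot_id")
  write_table(sim$truth$true_H, file.path(dir, "truth_H.tsv"),
              id_col = "factor")
  invisible(dir)
}
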