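# End-to-end orchestration: one structured config drives
# simulate -> read/filter/normalize -> unroll -> factorize -> scores ->
# enrichment -> figures, with every parameter and output hash logged in a
# manifest for reproducibility.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter explicit
#' (all seeds included). The default runs on a simulated Swiss roll;
#' real-data runs disable `simulate` and point `input` at 10x-style files
#' plus a base-layer mask.
#'
#' @param out_dir output directory
#' @param seed master seed; stage seeds are derived from it (sim = seed,
#'   nnmf = seed + 10, module controls = seed + 20, gsea = seed + 30)
#' @return nested configuration list
#' @export
default_config <- function(out_dir = "rollst_run", seed = 1L) {
  seed <- as.integer(seed)
  list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(enabled = TRUE, a = 60, b = 16, turns = 3,
                    point_step = 2, spot_step = 4,
                    depths = c(10, 25, 40), jitter = 1,
                    n_genes = 1200, theta = 10, baseline = 0.2),
    input = list(matrix = NULL, features = NULL, barcodes = NULL,
                 positions = NULL, mask = NULL, sample = "sample1"),
    filter = list(drop_mito = TRUE, mito_prefix = "mt-"),
    normalize = list(rv_threshold = 1.1),
    unroll = list(enabled = TRUE, k = 5, radius = 80, angle_min = 35,
                  angle_max = 125, tangent_window = 5, downscale = 1,
                  endpoint_mode = "largest"),
    factorize = list(K = 6, exclude_prefix = c("Rps", "Rpl"),
                     mode = "custom", seed = seed + 10L),
    pathways = list(model = "planted", per_sample = FALSE),
    modules = list(sets = "planted", n_bins = 24, n_ctrl = 100,
                   seed = seed + 20L),
    enrichment = list(enabled = TRUE, n_perm = 200, min_size = 1,
                      max_size = Inf, k_clusters = 3, seed = seed + 30L),
    figures = list(enabled = TRUE, format = "png")
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure and file existence before any compute, so a broken
#' config fails fast with the offending entry named.
#'
#' @param config configuration list (see [default_config()])
#' @return the config, invisibly
#' @export
validate_config <- function(config) {
  need <- c("out_dir", "seed", "simulate", "input", "filter", "normalize",
            "unroll", "factorize", "pathways", "modules", "enrichment",
            "figures")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    rollst_stop("rollst_config_error", "config misses section(s): %s",
                paste(miss, collapse = ", "))
  }
  if (!isTRUE(config$simulate$enabled)) {
    for (f in c("matrix", "features", "barcodes", "positions")) {
      p <- config$input[[f]]
      if (is.null(p) || !file.exists(p)) {
        rollst_stop("rollst_config_error",
                    "simulate disabled but input$%s is missing or absent on disk", f)
      }
    }
    if (isTRUE(config$unroll$enabled)) {
      p <- config$input$mask
      if (is.null(p) || !file.exists(p)) {
        rollst_stop("rollst_config_error",
                    "unroll enabled but input$mask is missing or absent on disk")
      }
    }
    if (identical(config$pathways$model, "planted") ||
        identical(config$modules$sets, "planted")) {
      rollst_stop("rollst_config_error",
                  "'planted' pathway model / gene sets require simulate$enabled")
    }
  }
  invisible(config)
}

#' Read / write a configuration as YAML
#' @param path YAML path
#' @return configuration list
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$enrichment$max_size) && is.character(cfg$enrichment$max_size)) {
    cfg$enrichment$max_size <- Inf
  }
  cfg
}

#' @rdname read_config
#' @param config configuration list
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rollst_stop("rollst_stage_error", "stage '%s' failed: %s", name,
                conditionMessage(e))
  })
}

#' Run the full pipeline from a configuration
#'
#' Executes (optional) simulation, read/filter/normalize, digital
#' unrolling, NNMF with top-gene signatures, pathway and module scoring
#' with correlation analysis, co-expression clustering plus preranked GSEA,
#' and figures. Every table is written as TSV; `manifest.json` records the
#' effective config and the md5 of each artifact (no timestamps, so reruns
#' are byte-identical).
#'
#' @param config configuration list (see [default_config()])
#' @return output directory, invisibly; results are also returned in the
#'   `"results"` attribute
#' @export
run_all <- function(config = default_config()) {
  validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(obj, name, id_col = "id") {
    p <- file.path(out, name)
    write_table(obj, p, id_col = id_col)
    artifacts <<- c(artifacts, p)
    p
  }

  truth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sim_cfg <- config$simulate
    sim <- run_stage("simulate", {
      spec <- spiral_spec(a = sim_cfg$a, b = sim_cfg$b, turns = sim_cfg$turns,
                          point_step = sim_cfg$point_step,
                          spot_step = sim_cfg$spot_step,
                          depths = sim_cfg$depths, jitter = sim_cfg$jitter,
                          seed = config$seed)
      s <- simulate_swissroll(spec, n_genes = sim_cfg$n_genes,
                              theta = sim_cfg$theta,
                              baseline = sim_cfg$baseline)
      emit_dataset(s, file.path(out, "sim"))
      s
    })
    ds <- sim$ds
    truth <- sim$truth
    mask <- truth$base_points
  } else {
    ds <- run_stage("read", read_spatial(config$input$matrix,
                                         config$input$features,
                                         config$input$barcodes,
                                         config$input$positions,
                                         sample = config$input$sample))
    mask <- config$input$mask
  }

  ds <- run_stage("filter", filter_genes(ds,
                                         drop_mito = config$filter$drop_mito,
                                         mito_prefix = config$filter$mito_prefix))
  norm <- run_stage("normalize",
                    normalize_counts(ds, rv_threshold = config$normalize$rv_threshold))

  coords <- NULL
  if (isTRUE(config$unroll$enabled)) {
    u <- config$unroll
    coords <- run_stage("unroll",
                        unroll_pipeline(ds, mask, k = u$k, radius = u$radius,
                                        angle_min = u$angle_min,
                                        angle_max = u$angle_max,
                                        downscale = u$downscale,
                                        endpoint_mode = u$endpoint_mode,
                                        tangent_window = u$tangent_window))
    emit(as.data.frame(coords), "coords.tsv")
  }

  model <- run_stage("factorize",
                     run_nnmf(norm, K = config$factorize$K,
                              seed = config$factorize$seed,
                              exclude_prefix = config$factorize$exclude_prefix,
                              mode = config$factorize$mode))
  emit(model$W, "model_W.tsv", id_col = "spot_id")
  emit(model$H, "model_H.tsv", id_col = "factor")
  sigs <- run_stage("signatures", {
    do.call(rbind, lapply(rownames(model$H), function(f) {
      sig <- tryCatch(select_top_genes(model, f),
                      rollst_degenerate_curve = function(e) NULL)
      if (is.null(sig)) return(NULL)
      data.frame(factor = f, knee_index = sig$knee_index,
                 top_genes = paste(sig$top_genes, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  emit(sigs, "signatures.tsv")

  pw_model <- run_stage("pathways", {
    if (identical(config$pathways$model, "planted")) {
      read_pathway_model(truth$pathway_model)
    } else read_pathway_model(config$pathways$model)
  })
  pw <- pathway_scores(norm, pw_model, per_sample = config$pathways$per_sample)
  emit(unclass(pw), "pathway_scores.tsv", id_col = "spot_id")

  sets <- run_stage("modules", {
    if (identical(config$modules$sets, "planted")) {
      truth$planted_sets
    } else read_gmt(config$modules$sets)
  })
  logn <- lognormalize(ds)
  ms <- sapply(names(sets), function(nm) {
    tryCatch(module_score(logn, sets[[nm]], n_bins = config$modules$n_bins,
                          n_ctrl = config$modules$n_ctrl,
                          seed = config$modules$seed),
             rollst_empty_error = function(e) rep(NA_real_, nrow(logn)))
  })
  rownames(ms) <- ds$spot_ids
  emit(ms, "module_scores.tsv", id_col = "spot_id")

  cors <- run_stage("correlations", {
    ok_pw <- colSums(!is.finite(pw)) == 0
    ok_ms <- colSums(!is.finite(ms)) == 0
    rbind(correlate(model$W, pw[, ok_pw, drop = FALSE]),
          correlate(ms[, ok_ms, drop = FALSE], pw[, ok_pw, drop = FALSE]))
  })
  emit(cors, "correlations.tsv")

  if (isTRUE(config$enrichment$enabled)) {
    e <- config$enrichment
    enr <- run_stage("enrichment",
                     gsea_factors(model, sets, n_perm = e$n_perm, seed = e$seed,
                                  min_size = e$min_size, max_size = e$max_size))
    emit(enr, "enrichment.tsv")
  }

  if (isTRUE(config$figures$enabled)) {
    run_stage("figures", {
      figdir <- file.path(out, "figures")
      dir.create(figdir, showWarnings = FALSE)
      for (f in colnames(model$W)) {
        plot_spatial(ds$pixel_xy, values = model$W[, f],
                     file = file.path(figdir, paste0(f, ".", config$figures$format)),
                     main = f)
      }
      if (!is.null(coords)) {
        plot_spatial(cbind(coords$x, coords$y), values = model$W[, 1],
                     file = file.path(figdir, paste0("unrolled_factor_1.",
                                                     config$figures$format)),
                     main = "factor_1 (unrolled)", invert_y = FALSE)
      }
    })
  }

  # out_dir is excluded from the recorded config so reruns of the same
  # analysis into different directories stay byte-identical
  cfg_rec <- config
  cfg_rec$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("rollst")),
    config = cfg_rec,
    artifacts = as.list(setNames(unname(tools::md5sum(artifacts)),
                                 basename(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  res <- list(ds = ds, norm = norm, coords = coords, model = model,
              pathway_scores = pw, module_scores = ms, correlations = cors,
              truth = truth)
  invisible(structure(out, results = res))
}

#' Plot spots in space
#'
#' Draws spots at their pixel (or unrolled) coordinates, colored either by
#' a continuous value (viridis ramp; non-finite values in the documented
#' missing-data color) or by precomputed colors (e.g. [embed_to_colors()]
#' hex strings). Image-frame plots invert the y axis so the rendering
#' matches the image orientation.
#'
#' @param xy n x 2 coordinate matrix
#' @param values continuous values, length n (ignored if `colors` given)
#' @param colors per-spot color strings
#' @param file output file; device chosen by extension (`.png` or `.pdf`)
#' @param main plot title
#' @param invert_y flip the y axis (TRUE for image-frame coordinates)
#' @param na_col color for non-finite values (default `"grey80"`)
#' @param cex point size
#' @return `file`, invisibly
#' @export
plot_spatial <- function(xy, values = NULL, colors = NULL, file,
                         main = "", invert_y = TRUE, na_col = "grey80",
                         cex = 0.6) {
  xy <- as.matrix(xy)
  if (is.null(colors)) {
    if (is.null(values)) rollst_stop("rollst_spec_error", "need values or colors")
    pal <- grDevices::hcl.colors(100, "viridis")
    ok <- is.finite(values)
    colors <- rep(na_col, length(values))
    if (any(ok)) {
      rng <- range(values[ok])
      idx <- if (diff(rng) == 0) rep(1L, sum(ok))
             else 1L + as.integer(99 * (values[ok] - rng[1]) / diff(rng))
      colors[ok] <- pal[idx]
    }
  }
  if (grepl("\\.pdf$", file, ignore.case = TRUE)) {
    grDevices::pdf(file, width = 7, height = 7)
  } else {
    grDevices::png(file, width = 700, height = 700)
  }
  on.exit(grDevices::dev.off())
  ylim <- range(xy[, 2], finite = TRUE)
  if (invert_y) ylim <- rev(ylim)
  plot(xy[, 1], xy[, 2], col = colors, pch = 16, cex = cex, asp = 1,
       ylim = ylim, xlab = "x", ylab = "y", main = main)
  invisible(file)
}
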