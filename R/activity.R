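# Footprint-based pathway activity scoring, binned-control module scores,
# correlation tables with BH adjustment, and the unit-cube color mapping.

#' Read a pathway weight model
#'
#' A footprint model is a long table `pathway, gene, weight`: for each
#' signalling pathway, the weights of its downstream (responsive) genes.
#' Only the `top_n` genes with the largest absolute weight are kept per
#' pathway (the published footprint models are used with their top 1000).
#'
#' @param path CSV path or a data.frame with those three columns
#' @param top_n genes kept per pathway (default 1000)
#' @return object of class `pathway_model` (data.frame)
#' @export
read_pathway_model <- function(path, top_n = 1000) {
  pm <- if (is.character(path)) read.csv(path, stringsAsFactors = FALSE) else as.data.frame(path)
  need <- c("pathway", "gene", "weight")
  if (!all(need %in% names(pm))) {
    rollst_stop("rollst_format_error", "pathway model needs columns: %s",
                paste(need, collapse = ", "))
  }
  if (any(!nzchar(pm$gene))) rollst_stop("rollst_format_error", "empty gene symbol in model")
  pm <- do.call(rbind, lapply(split(pm, pm$pathway), function(d) {
    d[order(-abs(d$weight)), ][seq_len(min(top_n, nrow(d))), ]
  }))
  rownames(pm) <- NULL
  class(pm) <- c("pathway_model", "data.frame")
  pm
}

#' Footprint pathway activity scores per spot
#'
#' `score(spot, pathway) = sum_g z(expr)[spot, g] * weight[pathway, g]` over
#' the genes shared between the model and the matrix, then z-scaled per
#' pathway across spots. When `per_sample` labels are given, both z-scalings
#' are done within each sample separately (each slide normalized on its
#' own).
#'
#' @param norm a `normalized_matrix`, or a plain spots x genes matrix
#' @param model a [read_pathway_model()] table (or data.frame with
#'   pathway/gene/weight)
#' @param per_sample optional per-spot sample labels; `TRUE` uses
#'   `norm$sample`
#' @param z_input z-scale the expression per gene before the dot product
#' @return matrix spots x pathways of class `score_table`; pathways with no
#'   shared genes give a NaN column with a warning
#' @export
pathway_scores <- function(norm, model, per_sample = FALSE, z_input = TRUE) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else as.matrix(norm)
  samples <- if (isTRUE(per_sample) && inherits(norm, "normalized_matrix")) {
    norm$sample
  } else if (is.character(per_sample) || is.factor(per_sample)) {
    as.character(per_sample)
  } else rep("all", nrow(values))
  model <- as.data.frame(model)
  pws <- unique(model$pathway)
  out <- matrix(NA_real_, nrow(values), length(pws),
                dimnames = list(rownames(values), pws))
  for (s in unique(samples)) {
    rows <- samples == s
    m <- values[rows, , drop = FALSE]
    mz <- if (z_input) zscale_cols(m) else m
    mz[!is.finite(mz)] <- 0
    for (pw in pws) {
      sub <- model[model$pathway == pw, ]
      shared <- intersect(sub$gene, colnames(m))
      if (length(shared) == 0) {
        warning(sprintf("pathway '%s' shares no genes with the matrix", pw))
        out[rows, pw] <- NaN
        next
      }
      w <- sub$weight[match(shared, sub$gene)]
      raw <- as.vector(mz[, shared, drop = FALSE] %*% w)
      s_sd <- sd(raw)
      out[rows, pw] <- if (is.finite(s_sd) && s_sd > 0) (raw - mean(raw)) / s_sd else 0
    }
  }
  structure(out, class = c("score_table", class(out)),
            scaling = "z_per_pathway")
}

#' Gene-set module score with expression-binned controls
#'
#' Genes are cut into `n_bins` equal-frequency bins by their average
#' expression; for each set gene, `n_ctrl` control genes are drawn (seeded,
#' with replacement when the bin is smaller than `n_ctrl`) from the same
#' bin, excluding the set genes themselves (at typical set-to-bin size
#' ratios, self-draws would bias the score toward zero). The score of a
#' spot is the mean expression of the set genes minus the mean expression
#' of the pooled control draws.
#'
#' @param expr spots x genes expression matrix; use log-normalized
#'   expression ([lognormalize()]) for count data
#' @param gene_set character vector of gene symbols; genes absent from the
#'   matrix are dropped with a warning
#' @param n_bins number of expression bins (default 24)
#' @param n_ctrl control genes drawn per set gene (default 100)
#' @param seed RNG seed for the control draws
#' @return named numeric vector, one score per spot
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  expr <- if (inherits(expr, "normalized_matrix")) expr$values else as.matrix(expr)
  present <- intersect(gene_set, colnames(expr))
  if (length(present) == 0) {
    rollst_stop("rollst_empty_error", "no gene of the set is present in the matrix")
  }
  if (length(present) < length(gene_set)) {
    warning(sprintf("%d set gene(s) absent from matrix; dropped",
                    length(gene_set) - length(present)))
  }
  avg <- colMeans(expr)
  # equal-frequency bins on average expression (ties broken by gene name
  # for determinism)
  ord <- order(avg, colnames(expr))
  bin <- integer(length(avg))
  bin[ord] <- ceiling(seq_along(avg) / (length(avg) / n_bins))
  names(bin) <- colnames(expr)
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- setdiff(names(bin)[bin == bin[g]], present)
    if (length(pool) == 0) pool <- setdiff(names(bin)[bin == bin[g]], g)
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  rowMeans(expr[, present, drop = FALSE]) - rowMeans(expr[, ctrl, drop = FALSE])
}

#' The 25-gene proliferating stem-cell signature
#'
#' Core signature of proliferating intestinal epithelial stem cells used to
#' localize regenerating crypts (packaged as a fixture gene set).
#'
#' @return character vector of 25 mouse gene symbols
#' @export
stem_signature <- function() {
  c("Hmgb2", "Ube2c", "Pclaf", "Stmn1", "Top2a", "Tubb5", "Birc5", "Mki67",
    "Cenpf", "Tuba1b", "Cenpa", "Ccdc34", "Tmpo", "Cdca3", "Ccna2", "Cdk1",
    "Nucks1", "Smc4", "Spc24", "Cdca8", "Nusap1", "Racgap1", "Pbk", "Kif15",
    "Mad2l1")
}

#' Pairwise Pearson correlations with BH adjustment
#'
#' All column pairs between two aligned tables; two-sided p-values;
#' Benjamini-Hochberg adjustment across the emitted set.
#'
#' @param table_a,table_b matrices or data.frames with aligned rows (spots)
#' @param method correlation method (default `"pearson"`)
#' @return data.frame with `row` (column of `table_a`), `col` (column of
#'   `table_b`), `r`, `p`, `padj`; zero-variance columns give `NA` with a
#'   warning
#' @export
correlate <- function(table_a, table_b, method = "pearson") {
  a <- as.matrix(table_a); b <- as.matrix(table_b)
  if (nrow(a) != nrow(b)) rollst_stop("rollst_spec_error", "row counts differ")
  if (is.null(colnames(a))) colnames(a) <- paste0("a", seq_len(ncol(a)))
  if (is.null(colnames(b))) colnames(b) <- paste0("b", seq_len(ncol(b)))
  grid <- expand.grid(row = colnames(a), col = colnames(b),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- a[, grid$row[i]]; y <- b[, grid$col[i]]
    if (sd(x) == 0 || sd(y) == 0 || anyNA(x) || anyNA(y)) {
      warning(sprintf("zero-variance or missing column in pair (%s, %s)",
                      grid$row[i], grid$col[i]))
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x, y, method = method)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(grid, r = res[, "r"], p = res[, "p"],
                    padj = p.adjust(res[, "p"], method = "BH"))
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Map a 3-D embedding to unit-cube colors
#'
#' Each embedding column is min-max rescaled into the unit cube and used as
#' the C, M, Y channels (K = 0) of a per-spot color, so transcriptionally
#' similar spots receive similar colors. Min-max scaling makes the result
#' invariant to per-column affine transforms.
#'
#' @param embedding spot x 3 matrix (finite)
#' @return list with `cmy` (spot x 3 matrix in `[0,1]`) and `hex`
#'   (per-spot R color strings); constant columns map to 0 with a warning
#' @export
embed_to_colors <- function(embedding) {
  emb <- as.matrix(embedding)
  if (ncol(emb) != 3) rollst_stop("rollst_spec_error", "embedding must have 3 columns")
  if (!all(is.finite(emb))) rollst_stop("rollst_spec_error", "non-finite embedding values")
  cmy <- apply(emb, 2, function(v) {
    rng <- diff(range(v))
    if (rng == 0) {
      warning("constant embedding column mapped to 0")
      rep(0, length(v))
    } else (v - min(v)) / rng
  })
  # CMY with K = 0: R = 1 - C, G = 1 - M, B = 1 - Y
  rgb_m <- 1 - cmy
  list(cmy = cmy,
       hex = grDevices::rgb(rgb_m[, 1], rgb_m[, 2], rgb_m[, 3]))
}
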