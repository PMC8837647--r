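# Gene-set analyses: co-expression clustering of gene panels (e.g. IBD risk
# genes), preranked permutation GSEA in factor loadings, and module-factor
# shared signatures.

#' Read gene sets
#'
#' GMT (set name, description, genes, tab-separated) or a one-symbol-per-line
#' file (a single set named after the file).
#'
#' @param path file path
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) rollst_stop("rollst_io_error", "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!any(grepl("\t", lines))) {
    out <- list(lines)
    names(out) <- tools::file_path_sans_ext(basename(path))
    return(out)
  }
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  if (anyDuplicated(names(sets))) rollst_stop("rollst_format_error", "duplicate set names")
  if (any(lengths(sets) == 0)) rollst_stop("rollst_format_error", "empty gene set")
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "rollst", sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Co-expression clustering of a gene panel
#'
#' Pearson correlation between the per-gene z-scaled expression profiles of
#' the panel genes, diagonal set to 0; Ward-linkage agglomerative
#' clustering (squared-distance update, `hclust` method `ward.D2`) on the
#' distance `1 - r`; tree cut into `k` clusters. The cluster with the
#' highest mean intra-cluster correlation is flagged as the co-expression
#' cluster (ties: lowest cluster id; singleton clusters rank last).
#'
#' @param norm `normalized_matrix` or spots x genes matrix
#' @param genes panel gene symbols; absent genes dropped with a warning
#' @param k number of clusters (default 3)
#' @return list with `clusters` (named integer vector), `cor_matrix`
#'   (diagonal zeroed), `selected` (flagged cluster id), `tree` (hclust)
#' @export
coexpression_clusters <- function(norm, genes, k = 3) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else as.matrix(norm)
  present <- intersect(genes, colnames(values))
  if (length(present) < length(genes)) {
    warning(sprintf("%d panel gene(s) absent from matrix; dropped",
                    length(genes) - length(present)))
  }
  if (length(present) < k) {
    rollst_stop("rollst_spec_error", "only %d gene(s) present; need >= k = %d",
                length(present), k)
  }
  z <- zscale_cols(values[, present, drop = FALSE])
  z[!is.finite(z)] <- 0
  r <- cor(z)
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  tree <- hclust(as.dist(1 - r), method = "ward.D2")
  cl <- cutree(tree, k = k)
  mean_intra <- vapply(sort(unique(cl)), function(ci) {
    g <- names(cl)[cl == ci]
    if (length(g) < 2) return(-Inf)
    sub <- r[g, g]
    mean(sub[upper.tri(sub)])
  }, 0)
  sel <- sort(unique(cl))[which.max(mean_intra)]
  list(clusters = cl, cor_matrix = r, selected = sel, tree = tree)
}

#' Module score of a selected co-expression cluster
#'
#' Thin wrapper around [module_score()] for the genes of a selected
#' cluster (e.g. the co-expressed subset of a disease risk panel).
#'
#' @param expr expression matrix (see [module_score()])
#' @param cluster_genes character vector (must be non-empty)
#' @param seed control-draw seed
#' @param ... passed to [module_score()]
#' @return per-spot score vector
#' @export
risk_module_score <- function(expr, cluster_genes, seed = 1L, ...) {
  if (length(cluster_genes) == 0) {
    rollst_stop("rollst_empty_error", "empty cluster gene set")
  }
  module_score(expr, cluster_genes, seed = seed, ...)
}

# Running-sum enrichment score of a set along a ranked statistic.
# stats_sorted: descending; in_set: logical same length.
running_es <- function(stats_sorted, in_set, weight = 1) {
  n <- length(stats_sorted)
  n_set <- sum(in_set)
  inc <- abs(stats_sorted)^weight * in_set
  denom <- sum(inc)
  if (denom == 0) inc[in_set] <- 1 / n_set else inc <- inc / denom
  dec <- (!in_set) / (n - n_set)
  rs <- cumsum(inc - dec)
  i <- which.max(abs(rs))
  list(es = rs[i], at = i, running = rs)
}

#' Preranked gene-set enrichment with permutation p-values
#'
#' Genes are ranked by descending statistic (ties broken by gene name for
#' determinism). The running sum increases by `|stat|^gsea_weight`
#' (normalized) at set genes and decreases uniformly elsewhere; the
#' enrichment score is the extremum of the running sum. Significance is a
#' permutation p-value over `n_perm` seeded gene-label permutations with
#' the `+1` correction, one-sided in the direction of the observed score;
#' BH adjustment is applied across the sets tested in the call.
#'
#' @param stats named numeric vector of per-gene statistics (e.g. one
#'   factor's loading row)
#' @param gene_sets named list of gene sets (a bare character vector is
#'   treated as one set)
#' @param n_perm number of permutations (default 1000)
#' @param seed RNG seed
#' @param gsea_weight exponent on `|stat|` (default 1; 0 = unweighted)
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked genes (sets outside the bounds are skipped with a reason)
#' @param on_empty `"error"` (default) or `"skip"`: behaviour for a set
#'   sharing no genes with the ranking
#' @return data.frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `p`, `padj`, `leading_edge` (comma-separated), `skipped`
#' @export
gsea_preranked <- function(stats, gene_sets, n_perm = 1000, seed = 1L,
                           gsea_weight = 1, min_size = 1, max_size = Inf,
                           on_empty = c("error", "skip")) {
  on_empty <- match.arg(on_empty)
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  ord <- order(-stats, names(stats))
  s <- stats[ord]
  genes <- names(s)
  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    inter <- intersect(gene_sets[[nm]], genes)
    if (length(inter) == 0) {
      if (on_empty == "error") {
        rollst_stop("rollst_empty_error",
                    "set '%s' shares no genes with the ranking", nm)
      }
      return(data.frame(set = nm, size = 0L, es = NA_real_, p = NA_real_,
                        leading_edge = "", skipped = "no shared genes",
                        stringsAsFactors = FALSE))
    }
    if (length(inter) < min_size || length(inter) > max_size) {
      return(data.frame(set = nm, size = length(inter), es = NA_real_,
                        p = NA_real_, leading_edge = "",
                        skipped = sprintf("size %d outside [%s, %s]",
                                          length(inter), min_size, max_size),
                        stringsAsFactors = FALSE))
    }
    in_set <- genes %in% inter
    obs <- running_es(s, in_set, gsea_weight)
    le <- if (obs$es >= 0) genes[seq_len(obs$at)][in_set[seq_len(obs$at)]]
          else genes[obs$at:length(genes)][in_set[obs$at:length(genes)]]
    # permutation ES evaluated in closed form at the set-gene positions:
    # the running-sum maximum is attained just after a set gene, the
    # minimum just before one, so only those 2m values need computing
    n <- length(genes)
    m <- length(inter)
    absw <- abs(s)^gsea_weight
    perm_es <- vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(n, m))
      w <- absw[pos]
      sumw <- sum(w)
      w <- if (sumw == 0) rep(1 / m, m) else w / sumw
      a <- cumsum(w) - (pos - seq_len(m)) / (n - m)
      b <- a - w
      amax <- max(a); bmin <- min(b)
      if (abs(amax) >= abs(bmin)) amax else bmin
    }, 0)
    p <- if (obs$es >= 0) (1 + sum(perm_es >= obs$es)) / (n_perm + 1)
         else (1 + sum(perm_es <= obs$es)) / (n_perm + 1)
    data.frame(set = nm, size = length(inter), es = obs$es, p = p,
               leading_edge = paste(le, collapse = ","), skipped = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out <- out[, c("set", "size", "es", "p", "padj", "leading_edge", "skipped")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' GSEA of gene sets across all factors of a model
#'
#' Runs [gsea_preranked()] on each factor's loading row and applies BH
#' across all (set, factor) pairs tested.
#'
#' @param model a `factor_model` (or a factors x genes loading matrix)
#' @param gene_sets named list of gene sets
#' @param ... passed to [gsea_preranked()]
#' @return `enrichment_result` data.frame with an extra `factor` column and
#'   BH recomputed over all pairs
#' @export
gsea_factors <- function(model, gene_sets, ...) {
  H <- if (inherits(model, "factor_model")) model$H else as.matrix(model)
  res <- lapply(rownames(H), function(f) {
    r <- gsea_preranked(setNames(H[f, ], colnames(H)), gene_sets,
                        on_empty = "skip", ...)
    r$factor <- f
    r
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, method = "BH")
  out <- out[, c("factor", "set", "size", "es", "p", "padj",
                 "leading_edge", "skipped")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Shared signature between a gene module and a factor
#'
#' Intersection of a module gene set with the factor's `top_k` highest-
#' loading genes; the spatial activity of the shared signature can then be
#' quantified with [module_score()].
#'
#' @param module_set character vector
#' @param model a `factor_model`
#' @param factor factor name or index
#' @param top_k number of top loading-ranked genes (default 100)
#' @return character vector (possibly empty), ordered by loading rank
#' @export
shared_signature <- function(module_set, model, factor, top_k = 100) {
  H <- if (inherits(model, "factor_model")) model$H else as.matrix(model)
  lo <- H[factor, ]
  top <- names(sort(lo, decreasing = TRUE))[seq_len(min(top_k, length(lo)))]
  top[top %in% module_set]
}
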