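# Reading 10x-style spatial inputs, gene filtering, and the
# variance-stabilizing normalization surrogate.

#' Construct a spatial dataset
#'
#' Container for a spot x gene count matrix with per-spot pixel coordinates.
#' All geometry in rollst uses the full-resolution image pixel frame: origin
#' top-left, x rightward (image column), y downward (image row), 0-based.
#'
#' @param counts non-negative integer matrix (spots x genes); dense or
#'   `Matrix` sparse
#' @param gene_ids character vector of gene symbols, one per column
#' @param spot_ids character vector of unique barcodes, one per row
#' @param pixel_xy numeric matrix (spots x 2) of pixel coordinates, columns
#'   `x`, `y`
#' @param sample per-spot sample label (recycled if length 1)
#' @param gene_biotypes optional named character vector mapping gene symbol
#'   to biotype
#' @return object of class `spatial_dataset`
#' @export
spatial_dataset <- function(counts, gene_ids, spot_ids, pixel_xy,
                            sample = "sample1", gene_biotypes = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(counts, "generalMatrix")
  if (any(counts@x < 0)) {
    rollst_stop("rollst_format_error", "counts contain negative entries")
  }
  if (length(gene_ids) != ncol(counts)) {
    rollst_stop("rollst_format_error",
                "gene_ids length (%d) != number of genes (%d)",
                length(gene_ids), ncol(counts))
  }
  if (length(spot_ids) != nrow(counts)) {
    rollst_stop("rollst_format_error",
                "spot_ids length (%d) != number of spots (%d)",
                length(spot_ids), nrow(counts))
  }
  if (anyDuplicated(spot_ids)) {
    rollst_stop("rollst_format_error", "spot_ids are not unique")
  }
  pixel_xy <- as.matrix(pixel_xy)
  if (nrow(pixel_xy) != nrow(counts) || ncol(pixel_xy) != 2) {
    rollst_stop("rollst_format_error", "pixel_xy must be n_spots x 2")
  }
  colnames(pixel_xy) <- c("x", "y")
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  structure(list(
    counts = counts,
    gene_ids = as.character(gene_ids),
    spot_ids = as.character(spot_ids),
    pixel_xy = pixel_xy,
    sample = rep_len(as.character(sample), nrow(counts)),
    gene_biotypes = gene_biotypes
  ), class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$sample))))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Read a 10x-style spatial dataset
#'
#' Reads a MatrixMarket count matrix (genes x spots on disk, transposed on
#' read to spots x genes), the matching `features.tsv` / `barcodes.tsv`, and
#' a `tissue_positions` CSV in the Visium dialect (columns `barcode`,
#' `in_tissue`, `array_row`, `array_col`, `pxl_row_in_fullres`,
#' `pxl_col_in_fullres`, with or without a header line). Spots flagged
#' `in_tissue == 0` are dropped.
#'
#' @param matrix_path path to the MTX file
#' @param features_path path to features TSV (columns: id, symbol, type;
#'   one- or two-column files are tolerated, the last available column is
#'   used as the symbol)
#' @param barcodes_path path to barcodes TSV
#' @param positions_path path to tissue positions CSV
#' @param sample sample label attached to every spot
#' @return a [spatial_dataset()]
#' @export
read_spatial <- function(matrix_path, features_path, barcodes_path,
                         positions_path, sample = "sample1") {
  for (p in c(matrix_path, features_path, barcodes_path, positions_path)) {
    if (!file.exists(p)) rollst_stop("rollst_io_error", "file not found: %s", p)
  }
  m <- Matrix::readMM(matrix_path)           # genes x spots on disk
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  bcs <- read.delim(barcodes_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (nrow(feats) != nrow(m)) {
    rollst_stop("rollst_format_error",
                "features TSV has %d rows but MTX declares %d genes",
                nrow(feats), nrow(m))
  }
  if (length(bcs) != ncol(m)) {
    rollst_stop("rollst_format_error",
                "barcodes TSV has %d rows but MTX declares %d spots",
                length(bcs), ncol(m))
  }
  symbols <- feats[[min(2L, ncol(feats))]]
  biotypes <- NULL
  if (ncol(feats) >= 4) biotypes <- setNames(feats[[4]], symbols)

  pos <- read_positions(positions_path)
  missing <- setdiff(bcs, pos$barcode)
  if (length(missing)) {
    rollst_stop("rollst_format_error",
                "barcode(s) in matrix but absent from positions: %s",
                paste(head(missing, 5), collapse = ", "))
  }
  pos <- pos[match(bcs, pos$barcode), ]
  keep <- pos$in_tissue != 0
  spatial_dataset(
    counts = Matrix::t(m)[keep, , drop = FALSE],
    gene_ids = symbols,
    spot_ids = bcs[keep],
    pixel_xy = cbind(x = pos$pxl_col_in_fullres[keep],
                     y = pos$pxl_row_in_fullres[keep]),
    sample = sample,
    gene_biotypes = biotypes
  )
}

# Visium positions files come with and without a header; sniff the first line.
read_positions <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("barcode", first, fixed = TRUE)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  pos <- read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(pos) != 6) {
      rollst_stop("rollst_format_error",
                  "positions CSV must have 6 columns, found %d", ncol(pos))
    }
    names(pos) <- cols
  }
  if (!all(cols %in% names(pos))) {
    rollst_stop("rollst_format_error", "positions CSV misses column(s): %s",
                paste(setdiff(cols, names(pos)), collapse = ", "))
  }
  pos
}

#' Default set of non-coding RNA biotypes
#'
#' Ensembl-style biotype labels treated as non-coding by [filter_genes()].
#' @return character vector
#' @export
noncoding_biotypes <- function() {
  c("lincRNA", "lncRNA", "miRNA", "snoRNA", "snRNA", "scaRNA", "sRNA",
    "rRNA", "Mt_rRNA", "Mt_tRNA", "misc_RNA", "antisense",
    "processed_transcript", "sense_intronic", "sense_overlapping",
    "bidirectional_promoter_lncRNA", "3prime_overlapping_ncRNA",
    "macro_lncRNA", "ribozyme", "TEC")
}

#' Filter genes by biotype and mitochondrial prefix
#'
#' Removes genes annotated with a non-coding RNA biotype, and (optionally)
#' mitochondrially encoded genes identified by symbol prefix. Genes missing
#' from the biotype table are retained with a warning rather than silently
#' dropped, so annotation gaps stay visible.
#'
#' @param ds a [spatial_dataset()]
#' @param biotype_table named character vector gene -> biotype; defaults to
#'   `ds$gene_biotypes`
#' @param drop_mito drop genes whose symbol starts with `mito_prefix`
#' @param mito_prefix case-insensitive symbol prefix, default `"mt-"`
#' @param noncoding biotype labels to treat as non-coding
#' @return filtered [spatial_dataset()] (spot set unchanged)
#' @export
filter_genes <- function(ds, biotype_table = ds$gene_biotypes,
                         drop_mito = TRUE, mito_prefix = "mt-",
                         noncoding = noncoding_biotypes()) {
  stopifnot(inherits(ds, "spatial_dataset"))
  keep <- rep(TRUE, length(ds$gene_ids))
  if (!is.null(biotype_table)) {
    bt <- biotype_table[ds$gene_ids]
    unknown <- is.na(bt)
    if (any(unknown)) {
      warning(sprintf("%d gene(s) missing from biotype table; retained",
                      sum(unknown)))
    }
    keep <- keep & (unknown | !(bt %in% noncoding))
  }
  if (isTRUE(drop_mito)) {
    keep <- keep & !startsWith(tolower(ds$gene_ids), tolower(mito_prefix))
  }
  if (!any(keep)) {
    rollst_stop("rollst_empty_error", "no genes left after filtering")
  }
  ds$counts <- ds$counts[, keep, drop = FALSE]
  ds$gene_ids <- ds$gene_ids[keep]
  if (!is.null(ds$gene_biotypes)) {
    ds$gene_biotypes <- ds$gene_biotypes[names(ds$gene_biotypes) %in% ds$gene_ids]
  }
  ds
}

#' Variance-stabilizing normalization (analytic Pearson residuals)
#'
#' Surrogate for regularized negative-binomial normalization: the expected
#' count of gene g in spot s is `mu = n_s * pi_g` (spot depth times the
#' gene's overall share of counts); per-gene method-of-moments
#' overdispersion estimates `max(0, sum((x - mu)^2 - mu) / sum(mu^2))` are
#' pooled into a single global (technical) overdispersion `alpha` (their
#' median - a per-gene estimate would absorb biological variance and
#' flatten all residual variances to ~1), and the returned values are
#' `(x - mu) / sqrt(mu + alpha * mu^2)`, clipped at
#' `+/- sqrt(n_spots)`. Genes whose residual variance exceeds
#' `rv_threshold` are flagged as variable features.
#'
#' @param ds a [spatial_dataset()] or a counts matrix (spots x genes)
#' @param rv_threshold residual-variance threshold for variable genes
#'   (default 1.1)
#' @param clip residual clipping bound; default `sqrt(n_spots)`
#' @return object of class `normalized_matrix`: list with `values` (dense
#'   spots x genes residual matrix), `variable_genes`, `residual_variance`,
#'   `sample`, and a `scaling` record of the method and parameters
#' @export
normalize_counts <- function(ds, rv_threshold = 1.1, clip = NULL) {
  if (inherits(ds, "spatial_dataset")) {
    counts <- ds$counts
    sample <- ds$sample
  } else {
    counts <- ds
    sample <- rep("sample1", nrow(counts))
  }
  x <- as.matrix(counts)
  if (length(x) == 0) rollst_stop("rollst_empty_error", "empty count matrix")
  n_s <- rowSums(x)
  if (any(n_s == 0)) {
    rollst_stop("rollst_empty_error", "spot(s) with zero total counts: %s",
                paste(head(rownames(x)[n_s == 0], 5), collapse = ", "))
  }
  pi_g <- colSums(x) / sum(x)
  mu <- outer(n_s, pi_g)                       # expected counts
  dev <- x - mu
  # per-gene MoM excess-variance estimates, pooled into one global
  # (technical) overdispersion: per-gene estimates would absorb biological
  # variance and flatten every residual variance to ~1
  alpha_g <- pmax(0, colSums(dev^2 - mu) / colSums(mu^2))
  alpha <- median(alpha_g)
  denom <- sqrt(mu + alpha * mu^2)
  denom[denom == 0] <- 1                       # all-zero gene: residual 0
  r <- dev / denom
  if (is.null(clip)) clip <- sqrt(nrow(x))
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  rv <- apply(r, 2, var)
  structure(list(
    values = r,
    variable_genes = colnames(x)[is.finite(rv) & rv > rv_threshold],
    residual_variance = setNames(rv, colnames(x)),
    sample = sample,
    scaling = list(method = "nb_pearson_residuals_mom",
                   rv_threshold = rv_threshold, clip = clip,
                   alpha = alpha)
  ), class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d spots x %d genes, %d variable (rv > %g)\n",
              nrow(x$values), ncol(x$values), length(x$variable_genes),
              x$scaling$rv_threshold))
  invisible(x)
}

#' Depth-normalized log expression
#'
#' `log1p(counts / depth * scale)`, the representation used for expression
#' binning in [module_score()].
#'
#' @param ds [spatial_dataset()] or counts matrix (spots x genes)
#' @param scale library-size scale factor
#' @return dense matrix spots x genes
#' @export
lognormalize <- function(ds, scale = 1e4) {
  counts <- if (inherits(ds, "spatial_dataset")) ds$counts else ds
  x <- as.matrix(counts)
  n_s <- rowSums(x)
  n_s[n_s == 0] <- 1
  log1p(x / n_s * scale)
}

#' Write a result table as TSV
#'
#' Plain TSV with a header; row identifiers (spot or gene ids) form the
#' first column. `NA`/`NaN` are written as the literal string `NA`.
#' Round-trips losslessly through [read_table()].
#'
#' @param obj matrix or data.frame; matrix rownames become the id column
#' @param path output path
#' @param id_col name of the identifier column, default `"id"`
#' @return `path`, invisibly
#' @export
write_table <- function(obj, path, id_col = "id") {
  if (is.matrix(obj)) {
    df <- data.frame(rownames(obj) %||% as.character(seq_len(nrow(obj))),
                     obj, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1] <- id_col
  } else {
    df <- as.data.frame(obj)
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) rollst_stop("rollst_io_error", "cannot write %s: %s",
                               path, conditionMessage(ok))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TSV written by [write_table()]
#' @param path TSV path
#' @return data.frame
#' @export
read_table <- function(path) {
  if (!file.exists(path)) rollst_stop("rollst_io_error", "file not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
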