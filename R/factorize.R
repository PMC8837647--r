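# Non-negative matrix factorization of the normalized spot x gene matrix
# into spatial programs, and knee-based selection of each factor's top
# contributing genes.

#' Non-negative double SVD initialization (NNDSVD)
#'
#' Boutsidis-Gallopoulos initialization: each SVD pair is split into its
#' positive and negative parts and the dominant part kept; zeros are filled
#' with a small seeded positive jitter so multiplicative structure can not
#' lock them at zero.
#'
#' @param x non-negative matrix
#' @param k rank
#' @param seed seed for the zero-fill jitter
#' @return list `W` (n x k), `H` (k x m), non-negative
#' @noRd
nndsvd_init <- function(x, k, seed = 1L) {
  sv <- svd(x, nu = k, nv = k)
  W <- matrix(0, nrow(x), k)
  H <- matrix(0, k, ncol(x))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      mp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      mn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (mp >= mn && mp > 0) {
        W[, j] <- sqrt(sv$d[j] * mp) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * mp) * vp / sqrt(sum(vp^2))
      } else if (mn > 0) {
        W[, j] <- sqrt(sv$d[j] * mn) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * mn) * vn / sqrt(sum(vn^2))
      }
    }
  }
  eps <- mean(x) * 1e-4 + 1e-10
  set.seed(seed)
  W[W <= 0] <- eps * runif(sum(W <= 0), 0.5, 1.5)
  H[H <= 0] <- eps * runif(sum(H <= 0), 0.5, 1.5)
  list(W = W, H = H)
}

#' NNMF deconvolution of a normalized expression matrix
#'
#' Factorizes the (clipped non-negative) variance-stabilized matrix into
#' `K` spatial programs by HALS coordinate descent minimizing the Frobenius
#' reconstruction error, from a deterministic NNDSVD initialization.
#' Ribosomal protein-coding genes (symbol prefixes `Rps`/`Rpl` by default)
#' are excluded before fitting. Deterministic given `seed`.
#'
#' @param norm a `normalized_matrix` from [normalize_counts()], or a plain
#'   matrix (spots x genes)
#' @param K rank (number of factors)
#' @param seed seed for initialization jitter
#' @param exclude_prefix gene-symbol prefixes removed before fitting
#'   (case-sensitive, ribosomal by default); `character(0)` disables
#' @param use_variable restrict to the variable genes of `norm`
#' @param nonneg `"clip"` (negative values set to 0, default) or `"shift"`
#'   (subtract the matrix minimum)
#' @param max_iter,tol HALS iteration cap and relative-error stop
#' @param mode free-text label recorded in the model (`"basic-3"`,
#'   `"per-sample-20"`, `"merged-20"`, `"custom"`)
#' @return object of class `factor_model`: `W` (spots x K, columns ordered
#'   by total weight, named `factor_1..K`), `H` (K x genes), `K`, `seed`,
#'   `mode`, `excluded_genes`, `rel_error`
#' @export
run_nnmf <- function(norm, K, seed = 1L, exclude_prefix = c("Rps", "Rpl"),
                     use_variable = TRUE, nonneg = c("clip", "shift"),
                     max_iter = 500L, tol = 1e-9, mode = "custom") {
  nonneg <- match.arg(nonneg)
  x <- if (inherits(norm, "normalized_matrix")) {
    v <- norm$values
    if (use_variable && length(norm$variable_genes)) {
      v[, norm$variable_genes, drop = FALSE]
    } else v
  } else as.matrix(norm)
  if (K < 1 || K > min(dim(x))) {
    rollst_stop("rollst_spec_error", "K = %d out of range for a %d x %d matrix",
                K, nrow(x), ncol(x))
  }
  if (!all(is.finite(x))) rollst_stop("rollst_spec_error", "non-finite values in input")
  excluded <- character(0)
  if (length(exclude_prefix) && !is.null(colnames(x))) {
    rib <- Reduce(`|`, lapply(exclude_prefix, function(p) startsWith(colnames(x), p)))
    excluded <- colnames(x)[rib]
    x <- x[, !rib, drop = FALSE]
  }
  x <- if (nonneg == "clip") pmax(x, 0) else x - min(x)

  init <- nndsvd_init(x, K, seed = seed)
  W <- init$W; H <- init$H
  xnorm2 <- sum(x^2)
  rel <- Inf
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    # update H given W
    WtX <- crossprod(W, x); WtW <- crossprod(W)
    for (j in seq_len(K)) {
      hj <- H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / max(WtW[j, j], eps)
      H[j, ] <- pmax(hj, 0)
    }
    # update W given H
    XHt <- x %*% t(H); HHt <- tcrossprod(H)
    for (j in seq_len(K)) {
      wj <- W[, j] + (XHt[, j] - W %*% HHt[, j]) / max(HHt[j, j], eps)
      W[, j] <- pmax(wj, 0)
    }
    if (it %% 10 == 0 || it == max_iter) {
      new_rel <- sum((x - W %*% H)^2) / xnorm2
      if (is.finite(rel) && rel - new_rel < tol * rel) { rel <- new_rel; break }
      rel <- new_rel
    }
  }
  # order factors by total contribution
  energy <- colSums(W) * rowSums(H)
  ord <- order(-energy)
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- paste0("factor_", seq_len(K))
  rownames(W) <- rownames(x)
  colnames(H) <- colnames(x)
  structure(list(W = W, H = H, K = K, seed = seed, mode = mode,
                 excluded_genes = excluded,
                 rel_error = sqrt(sum((x - W %*% H)^2) / xnorm2)),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model (%s): %d spots x %d factors x %d genes, rel. error %.3g\n",
              x$mode, nrow(x$W), x$K, ncol(x$H), x$rel_error))
  invisible(x)
}

#' Gaussian smoothing of a descending loading curve
#'
#' Drops non-positive loadings, sorts the rest by descending value, applies
#' the natural log, and convolves along the rank axis with a Gaussian
#' kernel of the given window length: support of `window` ranks
#' (truncation at `+/- window / 2`), `sigma = window / 4`, renormalized at
#' the curve edges.
#'
#' @param loadings named numeric vector (one factor's gene loadings)
#' @param window kernel window length (default 10)
#' @return data.frame with `rank`, `gene`, `value` (log loading) and
#'   `smoothed`
#' @export
smooth_loadings <- function(loadings, window = 10) {
  keep <- is.finite(loadings) & loadings > 0
  v <- sort(loadings[keep], decreasing = TRUE)
  if (length(v) == 0) rollst_stop("rollst_empty_error", "no positive loadings")
  y <- log(v)
  sigma <- window / 4
  radius <- ceiling(window / 2)
  kern <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  n <- length(y)
  sm <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - radius):min(n, i + radius)
    w <- kern[idx - i + radius + 1]
    sum(w * y[idx]) / sum(w)              # edge-renormalized
  }, 0)
  data.frame(rank = seq_len(n), gene = names(v), value = y, smoothed = sm,
             stringsAsFactors = FALSE)
}

#' Unit-invariant knee of a curve
#'
#' Both axes are min-max scaled to the unit square; the knee is the index
#' maximizing the perpendicular distance to the chord joining the first and
#' last scaled points, on the convex (knee) side of the chord - the signed
#' extreme-distance estimator. The sign matters on multi-level loading
#' curves: plateaus sit above the chord and would otherwise masquerade as
#' knees. Ties resolve to the smallest index. A curve that never dips below
#' its chord by more than `1e-12` (a straight ramp, or a purely concave
#' curve, which has no knee) raises a degenerate-curve error.
#'
#' @param y numeric vector of curve values (ordered), or a two-column
#'   matrix/data.frame of (x, y) pairs
#' @param x optional x positions (default: rank)
#' @return integer knee index (1-based)
#' @export
uik_knee <- function(y, x = NULL) {
  if (is.matrix(y) || is.data.frame(y)) {
    x <- as.numeric(y[, 1])
    y <- as.numeric(y[, 2])
  }
  if (is.null(x)) x <- seq_along(y)
  n <- length(y)
  if (n < 3) rollst_stop("rollst_spec_error", "need >= 3 points for a knee")
  if (diff(range(y)) == 0) {
    rollst_stop("rollst_degenerate_curve", "flat curve has no knee")
  }
  xs <- (x - min(x)) / diff(range(x))
  ys <- (y - min(y)) / diff(range(y))
  # signed perpendicular distance to the chord (first -> last); positive on
  # the convex side (below the chord for a descending curve)
  vx <- xs[n] - xs[1]; vy <- ys[n] - ys[1]
  len <- sqrt(vx^2 + vy^2)
  d <- (vy * (xs - xs[1]) - vx * (ys - ys[1])) / len
  if (max(d) < 1e-12) {
    rollst_stop("rollst_degenerate_curve",
                "curve does not bend below its chord; no knee")
  }
  which.max(d)
}

#' Select a factor's top contributing genes
#'
#' Composition drop-nonpositive -> sort -> log -> Gaussian smooth ->
#' unit-invariant knee. Top genes are the ranked genes up to and including
#' the knee.
#'
#' @param model a [run_nnmf()] `factor_model`, or a named loading vector
#' @param factor factor name or index (ignored when a vector is given)
#' @param window smoothing window (default 10)
#' @return object of class `factor_signature`: list with `factor`,
#'   `ranked_genes`, `knee_index`, `top_genes`
#' @export
select_top_genes <- function(model, factor = 1, window = 10) {
  loadings <- if (inherits(model, "factor_model")) model$H[factor, ] else model
  sm <- smooth_loadings(loadings, window = window)
  if (nrow(sm) < 3) {
    rollst_stop("rollst_spec_error",
                "only %d positive loadings; need >= 3", nrow(sm))
  }
  knee <- uik_knee(sm$smoothed, x = sm$rank)
  structure(list(factor = if (is.numeric(factor) && inherits(model, "factor_model"))
                   rownames(model$H)[factor] else as.character(factor),
                 ranked_genes = sm$gene,
                 knee_index = knee,
                 top_genes = sm$gene[seq_len(knee)]),
            class = "factor_signature")
}

#' @export
print.factor_signature <- function(x, ...) {
  cat(sprintf("factor_signature %s: knee at %d of %d ranked genes\n",
              x$factor, x$knee_index, length(x$ranked_genes)))
  invisible(x)
}

#' Match fitted factors to reference factors
#'
#' Optimal one-to-one assignment (Hungarian algorithm) maximizing the
#' Pearson correlation between fitted and reference activity columns.
#'
#' @param W fitted spot x K matrix
#' @param ref reference spot x K' matrix (same spots)
#' @return data.frame with `ref` (reference column), `fitted` (matched
#'   fitted column) and `r` (their correlation)
#' @export
match_factors <- function(W, ref) {
  r <- cor(ref, W)
  r[!is.finite(r)] <- -1
  sol <- clue::solve_LSAP(r - min(r) + 1, maximum = TRUE)
  data.frame(ref = colnames(ref) %||% as.character(seq_len(ncol(ref))),
             fitted = (colnames(W) %||% as.character(seq_len(ncol(W))))[as.integer(sol)],
             r = r[cbind(seq_len(ncol(ref)), as.integer(sol))],
             stringsAsFactors = FALSE)
}
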