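# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles and never call the package code paths they
# check.

# Benjamini-Hochberg step-up, textbook form.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Signed max-distance-to-chord knee on unit-scaled axes, plain O(n) loop.
oracle_knee <- function(y, x = seq_along(y)) {
  xs <- (x - min(x)) / (max(x) - min(x))
  ys <- (y - min(y)) / (max(y) - min(y))
  n <- length(y)
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(n)) {
    # distance of point i below the chord from (xs[1],ys[1]) to (xs[n],ys[n])
    vx <- xs[n] - xs[1]; vy <- ys[n] - ys[1]
    d <- (vy * (xs[i] - xs[1]) - vx * (ys[i] - ys[1])) / sqrt(vx^2 + vy^2)
    if (d > best + 1e-15) { best <- d; best_i <- i }
  }
  list(index = best_i, dist = best)
}

# Full running-sum GSEA enrichment score, literal cumulative sum.
oracle_es <- function(stats_sorted, in_set, weight = 1) {
  n <- length(stats_sorted)
  m <- sum(in_set)
  rs <- 0; best <- 0
  inc_total <- sum(abs(stats_sorted[in_set])^weight)
  for (i in seq_len(n)) {
    if (in_set[i]) {
      rs <- rs + if (inc_total == 0) 1 / m else abs(stats_sorted[i])^weight / inc_total
    } else {
      rs <- rs - 1 / (n - m)
    }
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# Greedy Ward (ward.D2 / Lance-Williams on squared dissimilarities)
# agglomeration from scratch; returns the partition at k clusters.
oracle_ward_cut <- function(d, k) {
  n <- nrow(d)
  D2 <- d^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  repeat {
    m <- length(active)
    if (m == k) break
    best <- Inf; bi <- bj <- NA
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (D2[i, j] < best - 1e-12) { best <- D2[i, j]; bi <- i; bj <- j }
    }
    ni <- sizes[bi]; nj <- sizes[bj]
    newD2 <- numeric(m)
    for (l in seq_len(m)) {
      if (l == bi || l == bj) next
      nl <- sizes[l]
      newD2[l] <- ((ni + nl) * D2[bi, l] + (nj + nl) * D2[bj, l] -
                     nl * D2[bi, bj]) / (ni + nj + nl)
    }
    keep <- setdiff(seq_len(m), c(bi, bj))
    merged <- c(active[[bi]], active[[bj]])
    D2 <- rbind(cbind(D2[keep, keep, drop = FALSE], newD2[keep]),
                c(newD2[keep], 0))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], ni + nj)
  }
  part <- integer(n)
  for (ci in seq_along(active)) part[active[[ci]]] <- ci
  part
}

# Adjusted Rand index from the contingency table.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Arc length of the Archimedean spiral r = a + b*theta by numeric quadrature.
oracle_spiral_arc <- function(a, b, theta_max) {
  integrate(function(th) sqrt((a + b * th)^2 + b^2), 0, theta_max,
            rel.tol = 1e-10)$value
}
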