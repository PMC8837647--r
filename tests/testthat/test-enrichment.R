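# enrichment: co-expression clustering, preranked GSEA, shared signatures.

test_that("GMT files round-trip and single-column set files parse", {
  sets <- list(alpha = c("a", "b", "c"), beta = c("d", "e"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_identical(read_gmt(gmt), sets)
  one <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("x", "y", "z"), one)
  got <- read_gmt(one)
  expect_identical(unname(got[[1]]), c("x", "y", "z"))
})

test_that("coexpression_clusters recovers planted blocks and matches the Ward oracle", {
  # three blocks of 10 genes driven by independent latent spatial signals
  set.seed(21)
  n_s <- 500
  lat <- matrix(rnorm(n_s * 3), n_s)
  x <- do.call(cbind, lapply(1:3, function(b)
    lat[, b] %o% rep(1, 10) + 0.5 * matrix(rnorm(n_s * 10), n_s)))
  colnames(x) <- paste0("blk", rep(1:3, each = 10), "_", 1:10)
  cx <- coexpression_clusters(x, colnames(x), k = 3)
  truth_blocks <- rep(1:3, each = 10)
  expect_equal(oracle_ari(cx$clusters, truth_blocks), 1)
  # the flagged cluster has the highest mean intra-cluster correlation
  intra <- vapply(1:3, function(ci) {
    g <- names(cx$clusters)[cx$clusters == ci]
    m <- cx$cor_matrix[g, g]
    mean(m[upper.tri(m)])
  }, 0)
  expect_equal(cx$selected, which.max(intra))
  expect_true(all(diag(cx$cor_matrix) == 0))

  # Ward agglomeration equals the from-scratch Lance-Williams oracle (<= 8 genes)
  set.seed(22)
  for (i in 1:5) {
    y <- matrix(rnorm(40 * 8), 40, dimnames = list(NULL, paste0("g", 1:8)))
    r <- cor(y); diag(r) <- 0
    tree <- hclust(as.dist(1 - r), method = "ward.D2")
    for (k in 2:4) {
      expect_equal(oracle_ari(cutree(tree, k),
                              oracle_ward_cut(as.matrix(as.dist(1 - r)), k)), 1)
    }
  }

  # k = number of genes: singletons
  cxs <- coexpression_clusters(x, colnames(x)[1:5], k = 5)
  expect_equal(sort(unname(cxs$clusters)), 1:5)
  # absent genes dropped with warning; too few is an error
  expect_warning(coexpression_clusters(x, c(colnames(x)[1:4], "ghost"), k = 3),
                 "absent")
  expect_error(suppressWarnings(coexpression_clusters(x, c("ghost1", "ghost2"), k = 2)),
               class = "rollst_spec_error")
})

test_that("risk_module_score lights up the planted follicle hotspots", {
  sim <- default_sim()
  logn <- lognormalize(sim$ds)
  sc <- risk_module_score(logn, sim$truth$planted_sets$follicle, seed = 4)
  hot <- sim$truth$true_W[, "follicle"] > 0.5
  null_sd <- sd(sc[!hot])
  expect_gte(mean(sc[hot]) - mean(sc[!hot]), 3 * null_sd)
  expect_error(risk_module_score(logn, character(0)),
               class = "rollst_empty_error")
  expect_identical(sc, risk_module_score(logn, sim$truth$planted_sets$follicle,
                                         seed = 4))
})

test_that("gsea_preranked matches the running-sum oracle and behaves at the extremes", {
  set.seed(31)
  # ES equals the literal cumulative-sum oracle on random rankings
  for (i in 1:25) {
    n <- sample(100:400, 1)
    stats <- setNames(rnorm(n), paste0("g", seq_len(n)))
    set <- sample(names(stats), sample(5:50, 1))
    r <- gsea_preranked(stats, list(s = set), n_perm = 10, seed = i)
    ord <- order(-stats, names(stats))
    expect_equal(r$es, oracle_es(stats[ord], names(stats)[ord] %in% set))
  }

  # maximal enrichment: set = top 20 of 1000
  stats <- setNames(sort(rnorm(1000), decreasing = TRUE), paste0("g", 1:1000))
  top <- gsea_preranked(stats, list(top = names(stats)[1:20]),
                        n_perm = 1000, seed = 1)
  expect_gte(top$es, 0.95)
  expect_equal(top$p, 1 / 1001)
  expect_identical(top$leading_edge,
                   paste(names(stats)[1:20], collapse = ","))

  # set/ranking mismatch and size gates
  expect_error(gsea_preranked(stats, list(bad = c("zz1", "zz2"))),
               class = "rollst_empty_error")
  skipped <- gsea_preranked(stats, list(small = names(stats)[1:5]),
                            n_perm = 10, seed = 1, min_size = 15,
                            max_size = 500)
  expect_true(nzchar(skipped$skipped))
  expect_true(is.na(skipped$es))
})

test_that("unweighted ES is antisymmetric under rank reversal and monotone-invariant", {
  set.seed(32)
  stats <- setNames(rnorm(300), paste0("g", 1:300))
  set <- sample(names(stats), 30)
  es_fwd <- gsea_preranked(stats, list(s = set), n_perm = 10, seed = 1,
                           gsea_weight = 0)$es
  es_rev <- gsea_preranked(-stats, list(s = set), n_perm = 10, seed = 1,
                           gsea_weight = 0)$es
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)

  # permutation p is invariant to monotone transforms of the statistic
  r1 <- gsea_preranked(stats, list(s = set), n_perm = 200, seed = 5,
                       gsea_weight = 0)
  r2 <- gsea_preranked(exp(stats) + 2, list(s = set), n_perm = 200, seed = 5,
                       gsea_weight = 0)
  expect_equal(r1$es, r2$es)
  expect_equal(r1$p, r2$p)
})

test_that("shared_signature intersects module sets with top factor genes", {
  H <- matrix(0, 2, 200, dimnames = list(c("f1", "f2"), paste0("g", 1:200)))
  H["f1", ] <- seq(200, 1)        # g1 has the top loading
  H["f2", ] <- seq_len(200)
  model <- structure(list(W = NULL, H = H), class = "factor_model")
  # disjoint set
  expect_length(shared_signature(c("zz1", "zz2"), model, "f1"), 0)
  # planted overlap: exactly the 30 module genes in the top 100
  mod <- paste0("g", c(1:30, 150:169))
  got <- shared_signature(mod, model, "f1", top_k = 100)
  expect_setequal(got, paste0("g", 1:30))
  # superset of the top genes: intersection is the top_k slice
  expect_setequal(shared_signature(paste0("g", 1:200), model, "f2", top_k = 10),
                  paste0("g", 191:200))
})

test_that("each planted marker set is most enriched in its own factor", {
  # factors of the default world overlap spatially (follicle hotspots sit
  # inside the lamina propria band), so cross-enrichment can reach nominal
  # significance; the strict uniqueness property is exercised on the
  # disjoint 20-factor world in the acceptance suite
  sim <- default_sim()
  model <- default_model()
  mt <- match_factors(model$W, sim$truth$true_W)
  sets <- sim$truth$planted_sets[mt$ref]
  res <- gsea_factors(model, sets, n_perm = 500, seed = 13)
  for (nm in mt$ref) {
    own <- mt$fitted[mt$ref == nm]
    sub <- res[res$set == nm, ]
    expect_equal(sub$factor[which.max(sub$es)], own)
    expect_lt(sub$padj[sub$factor == own], 0.05)
  }
})
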