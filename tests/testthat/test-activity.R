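# activity: footprint pathway scores, module scores, correlations, colors.

test_that("pathway_scores is exact on degenerate models and robust to missing genes", {
  set.seed(5)
  x <- matrix(rnorm(300 * 20), 300, dimnames = list(NULL, paste0("g", 1:20)))
  one_hot <- data.frame(pathway = "pw", gene = "g3", weight = 1)
  sc <- pathway_scores(x, one_hot)
  z3 <- (x[, "g3"] - mean(x[, "g3"])) / sd(x[, "g3"])
  expect_equal(unname(sc[, "pw"]), z3, tolerance = 1e-12)

  # (1, -1) weights: score proportional to the z-difference
  two <- data.frame(pathway = "pw", gene = c("g1", "g2"), weight = c(1, -1))
  sc2 <- pathway_scores(x, two)
  zdiff <- scale(x[, "g1"])[, 1] - scale(x[, "g2"])[, 1]
  expect_equal(cor(sc2[, "pw"], zdiff), 1, tolerance = 1e-12)

  # z-invariance to per-gene affine transforms of the input
  xa <- sweep(sweep(x, 2, runif(20, 1, 3), "*"), 2, runif(20, -5, 5), "+")
  expect_equal(pathway_scores(xa, two), sc2, tolerance = 1e-9)

  # pathway with no shared genes: NaN column and a warning
  miss <- data.frame(pathway = c("pw", "ghost"), gene = c("g1", "nope"),
                     weight = 1)
  expect_warning(sc3 <- pathway_scores(x, miss), "no genes")
  expect_true(all(is.nan(sc3[, "ghost"])))
  expect_false(anyNA(sc3[, "pw"]))
})

test_that("planted footprint activities are recovered from the simulation", {
  sim <- default_sim()
  norm <- default_norm()
  pw <- pathway_scores(norm, read_pathway_model(sim$truth$pathway_model))
  expect_gte(cor(pw[, "tnfa"], sim$truth$true_W[, "epi_dist"]), 0.9)
  expect_gte(cor(pw[, "wnt"], sim$truth$true_W[, "lp"]), 0.9)
  expect_gte(cor(pw[, "nfkb"], sim$truth$true_W[, "epi_dist"]), 0.9)
  # z-scaled columns
  expect_lt(max(abs(colMeans(pw))), 1e-8)
  expect_equal(unname(apply(pw, 2, sd)), rep(1, 4), tolerance = 1e-6)
})

test_that("module_score is null-centred, recovers planted shifts, and is seeded", {
  set.seed(8)
  n_s <- 400; n_g <- 500
  x <- matrix(rnorm(n_s * n_g), n_s, dimnames = list(NULL, paste0("g", 1:n_g)))
  # null: random set from the same distribution
  ms0 <- module_score(x, sample(colnames(x), 25), seed = 1)
  expect_lt(abs(mean(ms0)), 0.05)

  # planted +delta shift over bin-matched background. A shift applied to
  # every spot is absorbed by the expression binning (the set genes carry
  # their own controls along), so the recoverable quantity is the score
  # response: shifted minus unshifted spots.
  # heterogeneous base means spread the set genes across bins, so their
  # bin-matched controls are other genes of similar average expression
  delta <- 0.8
  base_means <- runif(n_g, 0, 20)
  xb <- sweep(x, 2, base_means, "+")
  set_genes <- sample(colnames(xb), 25)
  hot <- seq_len(n_s) <= n_s * 0.4
  xb[hot, set_genes] <- xb[hot, set_genes] + delta
  ms1 <- module_score(xb, set_genes, seed = 1)
  expect_equal(mean(ms1[hot]) - mean(ms1[!hot]), delta,
               tolerance = 0.1 * delta)

  # determinism and missing genes
  expect_identical(module_score(x, set_genes, seed = 3),
                   module_score(x, set_genes, seed = 3))
  expect_warning(module_score(x, c(set_genes, "absent"), seed = 1), "absent")
  expect_error(module_score(x, c("nope1", "nope2")),
               class = "rollst_empty_error")
})

test_that("stem_signature is the packaged 25-gene set and wires into the generator", {
  sgn <- stem_signature()
  expect_length(sgn, 25)
  expect_false(anyDuplicated(sgn) > 0)
  expect_true(all(nzchar(sgn)))
  expect_identical(sgn[1:5], c("Hmgb2", "Ube2c", "Pclaf", "Stmn1", "Top2a"))
  expect_setequal(default_sim()$truth$planted_sets$stem, sgn)
})

test_that("correlate matches the BH oracle and flags degenerate columns", {
  set.seed(10)
  a <- matrix(rnorm(500 * 3), 500, dimnames = list(NULL, c("a1", "a2", "a3")))
  b <- matrix(rnorm(500 * 4), 500, dimnames = list(NULL, paste0("b", 1:4)))
  res <- correlate(a, b)
  expect_equal(nrow(res), 12)
  expect_true(all(abs(res$r) < 0.15))
  expect_equal(res$padj, oracle_bh(res$p))
  expect_true(all(res$padj >= res$p))

  # column vs itself
  self <- correlate(a[, 1, drop = FALSE], a[, 1, drop = FALSE])
  expect_equal(self$r, 1)

  # zero-variance column: NA with warning, BH over the rest unharmed
  b2 <- cbind(b, flat = 1)
  expect_warning(correlate(a[, 1, drop = FALSE], b2[, "flat", drop = FALSE]),
                 "zero-variance")
  res2 <- suppressWarnings(correlate(a, b2))
  expect_true(all(is.na(res2$r[res2$col == "flat"])))
  expect_error(correlate(a, b[1:10, ]), class = "rollst_spec_error")
})

test_that("embed_to_colors rescales into the unit cube invariantly", {
  set.seed(2)
  emb <- matrix(rnorm(60), 20, 3)
  cl <- embed_to_colors(emb)
  expect_true(all(cl$cmy >= 0 & cl$cmy <= 1))
  # spot at the coordinate-wise minimum maps to channel 0
  imin <- apply(emb, 2, which.min)
  for (j in 1:3) expect_equal(cl$cmy[imin[j], j], 0)
  # identical rows, identical colors
  emb2 <- rbind(emb, emb[1, ])
  cl2 <- embed_to_colors(emb2)
  expect_equal(cl2$hex[21], cl2$hex[1])
  # per-column affine transforms leave colors unchanged
  emb3 <- sweep(sweep(emb, 2, c(2, 0.5, 10), "*"), 2, c(-1, 4, 0), "+")
  expect_equal(embed_to_colors(emb3)$hex, cl$hex)
  # degenerate inputs
  expect_warning(embed_to_colors(cbind(emb[, 1:2], 7)), "constant")
  expect_error(embed_to_colors(emb[, 1:2]), class = "rollst_spec_error")
  expect_error(embed_to_colors(matrix(c(1, Inf, 3, 4, 5, 6), 2)),
               class = "rollst_spec_error")
})

test_that("factor-pathway correlations reproduce the planted block structure", {
  sim <- default_sim()
  model <- default_model()
  pw <- pathway_scores(default_norm(), read_pathway_model(sim$truth$pathway_model))
  mt <- match_factors(model$W, sim$truth$true_W)
  f_inflam <- mt$fitted[mt$ref == "epi_dist"]
  f_regen <- mt$fitted[mt$ref == "lp"]
  cc <- cor(model$W[, c(f_inflam, f_regen)], pw[, c("tnfa", "nfkb", "wnt")])
  within <- c(cc[f_inflam, c("tnfa", "nfkb")], cc[f_regen, "wnt"])
  between <- c(cc[f_inflam, "wnt"], cc[f_regen, c("tnfa", "nfkb")])
  expect_gte(mean(within), 0.5)
  expect_lte(mean(between), 0.1)
})
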