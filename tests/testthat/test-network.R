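test_that("adjacency is |r|^power with unit diagonal", {
  x <- c(1, 2, 3, 4, 2, 6, 1, 3)
  y <- make_correlated_vector(x, 0.5)
  expr <- make_expr(rbind(x, y))
  a <- adjacency(expr, power = 2)
  expect_equal(a["g001", "g002"], 0.25, tolerance = 1e-12)
  expect_equal(diag(a), setNames(c(1, 1), rownames(expr)))

  # unsigned network: perfect anticorrelation saturates at 1
  expr2 <- make_expr(rbind(x, -x))
  expect_equal(adjacency(expr2, 1)["g001", "g002"], 1, tolerance = 1e-12)

  expr3 <- make_expr(rbind(x, rep(2, 8)))
  expect_error(adjacency(expr3, 2), "zero-variance")
  expect_error(adjacency(expr, power = 0), "positive")
})

test_that("TOM matches hand values and the brute-force oracle", {
  ones <- matrix(1, 3, 3)
  expect_equal(topological_overlap(ones)[1, 2], 1)    # (1+1)/(2+1-1)

  eye <- diag(3)
  expect_equal(unname(topological_overlap(eye)), diag(3))  # isolated genes

  for (s in 1:5) {
    a <- random_adjacency(10, seed = s)
    expect_equal(unname(topological_overlap(a)), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("average-linkage clustering has exact heights on small cases", {
  # two identical genes merge at height zero
  x <- rnorm(6)
  expr <- make_expr(rbind(x, x, rnorm(6)))
  tom <- topological_overlap(adjacency(expr, 6))
  tree <- cluster_genes(tom)
  expect_equal(tree$height[1], 0, tolerance = 1e-6)
  expect_true(all(diff(tree$height) >= -1e-12))

  # hand-computed average linkage on a fixed dissimilarity
  diss <- matrix(c(0, 0.1, 0.4,
                   0.1, 0, 0.6,
                   0.4, 0.6, 0), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tree2 <- cluster_genes(1 - diss)
  expect_equal(tree2$height, c(0.1, 0.5))  # then mean(0.4, 0.6)
})

test_that("static tree cut recovers planted blocks and handles edge settings", {
  n <- 5
  blocks <- matrix(1, 2 * n, 2 * n) * 0.001
  blocks[1:n, 1:n] <- 0.999
  blocks[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0.999
  diag(blocks) <- 1
  dimnames(blocks) <- list(paste0("g", 1:(2 * n)), paste0("g", 1:(2 * n)))
  tree <- cluster_genes(blocks)   # dissimilarity ~0 within, ~1 between
  mods <- cut_modules(tree, min_module_size = 3, cut_height = 0.5)
  expect_equal(length(module_names(mods)), 2)
  expect_equal(sum(mods$labels == "unassigned"), 0)
  expect_setequal(unname(mods$sizes), c(5, 5))

  all_un <- cut_modules(tree, min_module_size = 50)
  expect_true(all(all_un$labels == "unassigned"))
  zero_cut <- cut_modules(tree, min_module_size = 3, cut_height = 0)
  expect_true(all(zero_cut$labels == "unassigned"))
  expect_error(cut_modules(tree, min_module_size = 1), "at least 2")
})

test_that("eigengenes are PC1 sample scores with deterministic orientation", {
  # identical members: eigengene is the z-scored common profile, variance 1
  p <- c(3, 1, 4, 1, 5, 9)
  expr <- make_expr(rbind(p, p, p))
  res <- compute_eigengene(expr, rownames(expr))
  expect_equal(unname(res$eigengene), (p - mean(p)) / sd(p), tolerance = 1e-12)
  expect_equal(res$var_explained, 1)

  # orientation: negating every member leaves |eigengene| invariant and the
  # mean member correlation positive
  set.seed(8)
  expr2 <- make_expr(matrix(rnorm(20), 5, 4))
  r1 <- compute_eigengene(expr2, rownames(expr2))
  r2 <- compute_eigengene(-expr2, rownames(expr2))
  expect_equal(abs(r1$eigengene), abs(r2$eigengene), tolerance = 1e-12)
  expect_gt(mean(cor(t(expr2), r1$eigengene)), 0)

  # independent SVD oracle via prcomp on the transposed z-scored matrix
  set.seed(9)
  expr3 <- make_expr(matrix(rnorm(12), 3, 4))
  z <- t(scale(t(expr3)))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  oracle <- pc$x[, 1] / sd(pc$x[, 1])
  got <- compute_eigengene(expr3, rownames(expr3))$eigengene
  expect_equal(abs(unname(got)), abs(unname(oracle)), tolerance = 1e-10)
  expect_error(compute_eigengene(make_expr(matrix(1, 2, 4)), c("g001", "g002")),
               "degenerate")
})

test_that("eigengene-based merging is thresholded and chains greedily", {
  set.seed(10)
  e1 <- rnorm(20)
  mk <- function(e, n, sd) t(replicate(n, e + rnorm(20, sd = sd)))
  # modules a and b share a driver (identical eigengene), c is independent
  expr <- make_expr(rbind(mk(e1, 4, 0.01), mk(e1, 4, 0.01),
                          mk(rnorm(20), 4, 0.01)))
  labels <- setNames(rep(c("a", "b", "c"), each = 4), rownames(expr))
  mods <- module_eigengenes(expr, module_set(labels))
  merged <- merge_modules(expr, mods, merge_height = 0.2)
  expect_equal(length(module_names(merged)), 2)

  # dissimilarity 0.5 stays unmerged at height 0.3
  e2 <- make_correlated_vector(e1, 0.5, seed = 3)
  expr2 <- make_expr(rbind(mk(e1, 4, 1e-6), mk(e2, 4, 1e-6)))
  labels2 <- setNames(rep(c("a", "b"), each = 4), rownames(expr2))
  mods2 <- module_eigengenes(expr2, module_set(labels2))
  expect_equal(length(module_names(merge_modules(expr2, mods2, 0.3))), 2)

  # chained merging: pairwise diss (0.1, 0.1, 0.35) collapses to one module at
  # height 0.3 because the recomputed merged eigengene pulls c within reach
  C <- matrix(c(1, 0.9, 0.65, 0.9, 1, 0.9, 0.65, 0.9, 1), 3, 3)
  drivers <- make_correlated_data(40, C, seed = 6)
  expr3 <- make_expr(rbind(t(replicate(4, drivers[, 1] + rnorm(40, sd = 1e-6))),
                           t(replicate(4, drivers[, 2] + rnorm(40, sd = 1e-6))),
                           t(replicate(4, drivers[, 3] + rnorm(40, sd = 1e-6)))))
  labels3 <- setNames(rep(c("a", "b", "c"), each = 4), rownames(expr3))
  mods3 <- module_eigengenes(expr3, module_set(labels3))
  expect_equal(length(module_names(merge_modules(expr3, mods3, 0.3))), 1)
})

test_that("kME is the gene-eigengene correlation with its symmetries", {
  set.seed(11)
  e <- rnorm(30)
  expr <- make_expr(rbind(e, t(replicate(3, e + rnorm(30, sd = 0.3))), -e))
  labels <- setNames(c(rep("m", 4), "m"), rownames(expr))
  mods <- module_eigengenes(expr, module_set(labels))
  kme <- module_connectivity(expr, mods)
  eg <- mods$eigengenes["m", ]
  expect_equal(kme["g001", "m"], cor(e, eg), tolerance = 1e-12)
  expect_equal(kme["g005", "m"], -kme["g001", "m"], tolerance = 1e-12)

  exprz <- make_expr(rbind(e, rep(1, 30)))
  modsz <- module_set(setNames(c("m", "m"), rownames(exprz)))
  modsz$eigengenes <- mods$eigengenes
  expect_error(module_connectivity(exprz, modsz), "zero-variance")
})

test_that("percentile genes are selected by ceiling rank on kME order", {
  set.seed(12)
  e <- rnorm(20)
  n <- 10
  # graded noise gives a known kME order
  expr <- make_expr(t(sapply(seq_len(n), function(i) e + rnorm(20, sd = 0.05 * i))))
  tpm <- rhizomod:::expr_matrix(2^expr, "tpm")
  labels <- setNames(rep("m", n), rownames(expr))
  mods <- module_eigengenes(expr, module_set(labels))
  kme <- module_connectivity(expr, mods)
  ranked <- rank_module_genes(mods, kme, "m")

  prof <- percentile_gene_profile(tpm, mods, kme, "m", reference_gene = ranked[1],
                                  percentiles = c(1, 50, 100))
  expect_equal(unique(prof$gene[prof$percentile == 1]), ranked[1])
  expect_equal(unique(prof$gene[prof$percentile == 50]), ranked[5])   # ceil(0.5*10)
  expect_equal(unique(prof$gene[prof$percentile == 100]), ranked[10])
  self <- prof$ratio[prof$percentile == 1]
  expect_equal(self, rep(1, 20))
})

test_that("soft-threshold scan scores power-law connectivity and degenerate input", {
  # scale-free fit: frequencies engineered as a power law of connectivity
  k <- rep(1:10, times = round(200 * (1:10)^-2))
  fit <- scale_free_fit(k, n_bins = 10)
  x <- log10(tapply(k, cut(k, 10, include.lowest = TRUE), mean))
  y <- log10(tapply(k, cut(k, 10, include.lowest = TRUE), length))
  oracle <- summary(lm(y[is.finite(y)] ~ x[is.finite(y)]))$r.squared
  expect_equal(fit, oracle, tolerance = 1e-12)
  expect_gt(fit, 0.9)

  set.seed(13)
  expr <- make_expr(matrix(rnorm(35 * 10), 35, 10))
  scan <- pick_soft_threshold(expr, powers = c(2, 4, 6), target_r2 = -1)
  expect_equal(scan$chosen_power, 2)  # vacuous criterion takes the first power
  expect_true(scan$chosen_power %in% scan$scan$power)

  # two blocks of perfectly correlated genes: constant within-block k must
  # not crash the binning
  e1 <- rnorm(10)
  e2 <- rnorm(10)
  expr2 <- make_expr(rbind(t(replicate(16, e1)) * runif(16, 0.5, 2),
                           t(replicate(16, e2)) * runif(16, 0.5, 2)))
  expect_no_error(pick_soft_threshold(expr2, powers = c(1, 6)))

  exprc <- make_expr(rbind(matrix(rnorm(34 * 10), 34, 10), rep(1, 10)))
  expect_error(pick_soft_threshold(exprc), "constant-expression")
})

test_that("gene order permutation permutes module labels consistently", {
  expr <- two_block_expr(n_per = 16, n_samples = 20)
  res1 <- detect_modules(expr, powers = c(6), min_module_size = 5,
                         cut_height = 0.9)
  set.seed(14)
  perm <- sample(nrow(expr))
  res2 <- detect_modules(expr[perm, ], powers = c(6), min_module_size = 5,
                         cut_height = 0.9)
  g <- rownames(expr)
  # same partition of genes, possibly different module names
  tab <- table(res1$modules$labels[g], res2$modules$labels[g])
  expect_equal(sum(tab > 0), length(module_names(res1$modules)))
})
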