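test_that("module-factor correlations handle signs and missing values", {
  set.seed(40)
  f <- runif(20, 1, 100)
  eg <- matrix(c((f - mean(f)) / sd(f), -(f - mean(f)) / sd(f)), 2, 20,
               byrow = TRUE, dimnames = list(c("a", "b"), sprintf("s%02d", 1:20)))
  fac <- data.frame(x = f, y = rnorm(20), row.names = sprintf("s%02d", 1:20))
  fac$y[3] <- NA
  ct <- module_factor_correlations(eg, fac)
  expect_equal(ct$r["a", "x"], 1, tolerance = 1e-12)
  expect_equal(ct$r["b", "x"], -1, tolerance = 1e-12)
  expect_equal(ct$n["a", "y"], 19)   # pairwise-complete bookkeeping
  expect_equal(ct$n["a", "x"], 20)

  fac2 <- data.frame(x = rep(1, 20), row.names = sprintf("s%02d", 1:20))
  expect_warning(ct2 <- module_factor_correlations(eg, fac2), "constant")
  expect_true(is.na(ct2$r["a", "x"]))
})

test_that("collinearity pruning drops the later factor at |r| >= 0.9", {
  set.seed(41)
  x <- rnorm(30)
  dup <- data.frame(a = x, b = x, row.names = sprintf("s%02d", 1:30))
  res <- drop_collinear_factors(dup)
  expect_equal(res$retained, "a")
  expect_equal(res$dropped$dropped, "b")

  # |r| = 0.89 is below the inclusive threshold: both kept
  pair <- make_correlated_data(30, matrix(c(1, 0.89, 0.89, 1), 2), seed = 4)
  res2 <- drop_collinear_factors(as.data.frame(pair))
  expect_equal(res2$retained, c("f1", "f2"))

  # chain a~b 0.95, b~c 0.95, a~c 0.85 (below threshold): b dropped because
  # of a, then c is compared only against the retained a and survives
  C <- matrix(c(1, 0.95, 0.85, 0.95, 1, 0.95, 0.85, 0.95, 1), 3, 3)
  chain <- as.data.frame(make_correlated_data(40, C, seed = 5))
  res3 <- drop_collinear_factors(chain)
  expect_equal(res3$retained, c("f1", "f3"))
  expect_equal(res3$dropped$dropped, "f2")
})

test_that("min-max standardization is the stated affine map", {
  expect_equal(standardize_minmax(c(0, 5, 10)), c(-50, 0, 50))
  expect_equal(standardize_minmax(c(1, 2, 4)), c(-50, -50/3, 50), tolerance = 1e-12)
  v <- c(-50, -12, 3, 50)
  expect_equal(standardize_minmax(v), v)
  expect_error(standardize_minmax(rep(3, 5)), "constant")

  # affine: correlations are untouched
  set.seed(42)
  m <- matrix(rnorm(60), 20, 3)
  m2 <- apply(m, 2, standardize_minmax)
  expect_equal(cor(m), cor(m2), tolerance = 1e-12)
})

test_that("module regression recovers exact and closed-form fits", {
  set.seed(43)
  n <- 40
  sn <- sprintf("s%02d", 1:n)
  f1 <- rnorm(n)
  fac <- data.frame(f1 = f1, row.names = sn)
  eg <- setNames(f1, sn)
  fit <- suppressWarnings(fit_module_regression(eg, fac))  # perfect fit
  expect_equal(fit$coefficients$coefficient[fit$coefficients$factor == "f1"], 1,
               tolerance = 1e-10)
  expect_equal(fit$coefficients$coefficient[1], 0, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # orthogonal factors, response = f1 - f2: closed-form OLS coefficients
  X <- make_correlated_data(n, diag(2), seed = 6)
  fac2 <- as.data.frame(X)
  rownames(fac2) <- sn
  y <- setNames(X[, 1] - X[, 2], sn)
  fit2 <- suppressWarnings(fit_module_regression(y, fac2, standardize = FALSE))
  co <- setNames(fit2$coefficients$coefficient, fit2$coefficients$factor)
  expect_equal(unname(co[c("f1", "f2")]), c(1, -1), tolerance = 1e-10)

  # normal-equations oracle
  set.seed(44)
  fac3 <- as.data.frame(matrix(rnorm(n * 3), n, 3))
  colnames(fac3) <- paste0("f", 1:3)
  rownames(fac3) <- sn
  y3 <- setNames(rnorm(n), sn)
  fit3 <- fit_module_regression(y3, fac3, standardize = FALSE)
  Xd <- cbind(1, as.matrix(fac3))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y3)
  expect_equal(fit3$coefficients$coefficient, as.numeric(beta), tolerance = 1e-10)

  # independent response: R^2 stays small at n = 200
  set.seed(45)
  snl <- sprintf("s%03d", 1:200)
  facl <- as.data.frame(matrix(rnorm(200 * 3), 200, 3))
  rownames(facl) <- snl
  yl <- setNames(rnorm(200), snl)
  expect_lt(fit_module_regression(yl, facl)$r_squared, 0.1)

  dupf <- data.frame(a = f1, b = f1, row.names = sn)
  expect_error(fit_module_regression(eg, dupf, standardize = FALSE),
               "rank-deficient")
})

test_that("correlation-matrix PCA matches an eigendecomposition oracle", {
  r <- matrix(c(0.9, -0.2, 0.9, -0.2, 0.1, 0.8), 3, 2, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), c("f1", "f2")))
  ct <- structure(list(r = r, p = r * 0, n = r * 0 + 10),
                  class = "correlation_table")
  bi <- correlation_pca_biplot(ct)
  cen <- scale(r, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(cen))
  expect_equal(unname(bi$var_explained),
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-10)
  expect_equal(abs(unname(bi$module_scores[, 1])),
               abs(unname((cen %*% ev$vectors)[, 1])), tolerance = 1e-10)

  # identical correlation rows give identical scores (m1 == m2 here)
  r2 <- rbind(m1 = c(0.5, -0.5), m2 = c(0.5, -0.5), m3 = c(-1, 1))
  ct2 <- structure(list(r = r2, p = r2 * 0, n = r2 * 0 + 10),
                   class = "correlation_table")
  bi2 <- correlation_pca_biplot(ct2)
  expect_equal(bi2$module_scores["m1", ], bi2$module_scores["m2", ])
  expect_equal(bi2$var_explained[1], 1, tolerance = 1e-12)  # rank 1
})

test_that("gene-eigengene cross-correlation counts and bins are conserved", {
  set.seed(46)
  eg <- rnorm(100)
  same <- make_expr(t(replicate(5, eg)))
  res <- gene_eigengene_crosscorrelation(same, rownames(same), eg)
  expect_equal(res$per_gene$r, rep(1, 5), tolerance = 1e-12)
  expect_equal(res$counts$positive, c(5L, 5L))
  expect_equal(sum(res$histogram$count), 5)

  noise <- make_expr(matrix(rnorm(100 * 400), 400, 100))
  resn <- gene_eigengene_crosscorrelation(noise, rownames(noise), eg,
                                          alpha_levels = 0.01)
  frac <- (resn$counts$positive + resn$counts$negative) / 400
  expect_lt(frac, 0.04)   # null calibration around the nominal 1%
  expect_equal(sum(resn$histogram$count), 400)
})

test_that("eigengene correlation handles identity, negation, orthogonality", {
  set.seed(47)
  a <- setNames(rnorm(10), paste0("s", 1:10))
  expect_equal(eigengene_correlation(a, a)$r, 1, tolerance = 1e-12)
  expect_equal(eigengene_correlation(a, -a)$r, -1, tolerance = 1e-12)
  b <- residuals(lm(rnorm(10) ~ a))
  names(b) <- names(a)
  expect_equal(eigengene_correlation(a, b)$r, 0, tolerance = 1e-12)
  expect_error(eigengene_correlation(a[1:3], a[1:3]), "at least 4")
})
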