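#' Pairwise correlations between module eigengenes and soil/plant factors
#'
#' Pairwise-complete Pearson correlation with a two-sided t-test p-value per
#' module-by-factor cell; the number of complete pairs is recorded per cell.
#' Constant factors or eigengenes yield missing cells with a warning.
#'
#' @param eigengenes module-by-sample matrix.
#' @param factors sample-by-factor data.frame (missing values allowed).
#' @return object of class `correlation_table`: list of module-by-factor
#'   matrices `r`, `p`, `n`.
#' @export
module_factor_correlations <- function(eigengenes, factors) {
  shared <- intersect(colnames(eigengenes), rownames(factors))
  if (length(shared) < 4L) stop("need at least 4 shared samples", call. = FALSE)
  E <- eigengenes[, shared, drop = FALSE]
  F_ <- as.matrix(factors[shared, , drop = FALSE])
  mods <- rownames(E)
  facs <- colnames(F_)
  r <- p <- n <- matrix(NA_real_, length(mods), length(facs),
                        dimnames = list(mods, facs))
  warned <- character()
  for (m in mods) for (f in facs) {
    ok <- is.finite(E[m, ]) & is.finite(F_[, f])
    n[m, f] <- sum(ok)
    if (sum(ok) < 4L) next
    if (sd(E[m, ok]) == 0 || sd(F_[ok, f]) == 0) {
      warned <- c(warned, paste0(m, "/", f))
      next
    }
    r[m, f] <- cor(E[m, ok], F_[ok, f])
    p[m, f] <- cor_pvalue(r[m, f], sum(ok))
  }
  if (length(warned)) {
    warning("constant input, cell(s) left missing: ",
            paste(head(warned, 5L), collapse = ", "))
  }
  structure(list(r = r, p = p, n = n), class = "correlation_table")
}

#' Drop collinear factors
#'
#' Scans factor pairs in input column order; whenever two retained factors
#' correlate with `|r| >= r_cut` (pairwise-complete), the later-listed one is
#' dropped. Deterministic and auditable.
#'
#' @param factors sample-by-factor data.frame (>= 2 factors).
#' @param r_cut absolute-correlation exclusion threshold (default 0.9,
#'   boundary inclusive).
#' @return list with `retained` (factor names), `dropped` (data.frame
#'   `dropped`, `because_of`, `r`), and `factors` (the pruned table).
#' @export
drop_collinear_factors <- function(factors, r_cut = 0.9) {
  nm <- colnames(factors)
  if (length(nm) < 2L) stop("need at least 2 factors", call. = FALSE)
  cm <- cor(as.matrix(factors), use = "pairwise.complete.obs")
  retained <- character()
  dropped <- data.frame(dropped = character(), because_of = character(),
                        r = numeric())
  for (f in nm) {
    clash <- retained[!is.na(cm[f, retained]) & abs(cm[f, retained]) >= r_cut]
    if (length(clash)) {
      dropped <- rbind(dropped, data.frame(dropped = f, because_of = clash[1L],
                                           r = cm[f, clash[1L]]))
    } else {
      retained <- c(retained, f)
    }
  }
  list(retained = retained, dropped = dropped,
       factors = factors[, retained, drop = FALSE])
}

#' Min-max standardization to the [-50, +50] range
#'
#' Linear map sending the minimum to -50 and the maximum to +50:
#' \eqn{v' = -50 + 100 (v - \min v) / (\max v - \min v)}. Affine, so the
#' correlation structure among variables is unchanged.
#'
#' @param x numeric vector with `max > min`.
#' @return standardized vector.
#' @export
standardize_minmax <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("cannot standardize a constant vector (zero range)", call. = FALSE)
  }
  -50 + 100 * (x - rng[1L]) / diff(rng)
}

#' Multiple linear regression of a module eigengene on environmental factors
#'
#' Ordinary least squares with intercept on complete cases, after min-max
#' standardizing the response and every factor to [-50, +50]. Per-coefficient
#' two-sided t-tests, R-squared and the overall F-test are reported with the
#' conventional significance stars (* p<0.05, ** p<0.01, *** p<0.001).
#' Factors should be collinearity-pruned first ([drop_collinear_factors()]).
#'
#' @param eigengene named per-sample eigengene vector.
#' @param factors sample-by-factor data.frame.
#' @param standardize min-max standardize response and factors (default TRUE).
#' @return object of class `regression_result`: list with `coefficients`
#'   (data.frame `factor`, `coefficient`, `t`, `p`, `stars`, intercept row
#'   included), `r_squared`, `f_p`, `n`, and the underlying `fit`.
#' @export
fit_module_regression <- function(eigengene, factors, standardize = TRUE) {
  shared <- intersect(names(eigengene), rownames(factors))
  df <- data.frame(.response = eigengene[shared],
                   factors[shared, , drop = FALSE], check.names = FALSE)
  df <- df[complete.cases(df), , drop = FALSE]
  p <- ncol(factors)
  if (nrow(df) <= p + 1L) stop("need n > p + 1 complete cases", call. = FALSE)
  if (standardize) df[] <- lapply(df, standardize_minmax)
  X <- as.matrix(df[, -1L, drop = FALSE])
  if (qr(cbind(1, X))$rank < p + 1L) {
    stop("rank-deficient design matrix; run drop_collinear_factors() first",
         call. = FALSE)
  }
  fit <- lm(.response ~ ., data = df)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(factor = c("(Intercept)", colnames(X)),
                      coefficient = ct[, 1L], t = ct[, 3L], p = ct[, 4L],
                      stars = p_stars(ct[, 4L]), row.names = NULL)
  f_p <- unname(pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                   lower.tail = FALSE))
  structure(list(coefficients = coefs, r_squared = sm$r.squared, f_p = f_p,
                 n = nrow(df), fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("module regression: n = %d, R^2 = %.3f, overall F p = %.3g\n",
              x$n, x$r_squared, x$f_p))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' PCA biplot of the module-by-factor correlation matrix
#'
#' Principal component analysis of the `r` matrix of a
#' [module_factor_correlations()] result, with modules as observations and
#' columns centered but not rescaled (cells are already on the common r
#' scale). Returns module scores and factor loadings for the leading
#' components.
#'
#' @param cortable a `correlation_table`.
#' @param n_components components to return (default 2).
#' @param impute_missing replace missing cells by 0 with a warning
#'   (default FALSE: missing cells are an error).
#' @return object of class `biplot_result`: `module_scores`,
#'   `factor_loadings`, `var_explained` (non-increasing fractions).
#' @export
correlation_pca_biplot <- function(cortable, n_components = 2,
                                   impute_missing = FALSE) {
  r <- cortable$r
  if (nrow(r) < 3L) stop("need at least 3 modules", call. = FALSE)
  if (anyNA(r)) {
    if (!impute_missing) stop("missing cells; set impute_missing = TRUE", call. = FALSE)
    warning("missing correlation cells imputed by 0")
    r[is.na(r)] <- 0
  }
  pc <- prcomp(r, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  structure(list(module_scores = pc$x[, seq_len(nc), drop = FALSE],
                 factor_loadings = pc$rotation[, seq_len(nc), drop = FALSE],
                 var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nc)]),
            class = "biplot_result")
}

#' Gene-eigengene cross-correlation distribution
#'
#' Correlates every gene of a source module with a target module's eigengene,
#' reporting per-gene r and p, counts of significantly positive and negative
#' genes at each alpha level, and a fixed-width histogram of the r values for
#' frequency plots.
#'
#' @param expr expression matrix.
#' @param source_genes genes of the source module.
#' @param target_eigengene per-sample eigengene of the target module.
#' @param alpha_levels significance levels (default `c(0.01, 0.001)`).
#' @param bin_width histogram bin width over [-1, 1] (default 0.1).
#' @return list with `per_gene` (data.frame `gene`, `r`, `p`), `counts`
#'   (data.frame `alpha`, `positive`, `negative`), and `histogram`
#'   (data.frame `mid`, `count`; counts sum to the number of source genes).
#' @export
gene_eigengene_crosscorrelation <- function(expr, source_genes, target_eigengene,
                                            alpha_levels = c(0.01, 0.001),
                                            bin_width = 0.1) {
  x <- expr[source_genes, , drop = FALSE]
  r <- as.numeric(cor(t(x), target_eigengene))
  p <- cor_pvalue(r, ncol(x))
  counts <- data.frame(alpha = alpha_levels,
                       positive = vapply(alpha_levels, function(a) sum(p < a & r > 0), 0L),
                       negative = vapply(alpha_levels, function(a) sum(p < a & r < 0), 0L))
  breaks <- seq(-1, 1, by = bin_width)
  h <- hist(r, breaks = breaks, plot = FALSE)
  list(per_gene = data.frame(gene = source_genes, r = r, p = p),
       counts = counts,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Correlation between two eigengenes
#'
#' @param a,b named per-sample eigengene vectors (>= 4 shared samples).
#' @return list with `r`, `p`, `n`.
#' @export
eigengene_correlation <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]
    b <- b[shared]
  }
  if (length(a) < 4L) stop("need at least 4 shared samples", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) stop("degenerate (constant) eigengene", call. = FALSE)
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' @importFrom graphics hist
NULL
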