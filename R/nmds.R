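#' Non-metric multidimensional scaling by stress majorization
#'
#' Minimizes Kruskal stress-1,
#' \deqn{\sigma_1 = \sqrt{\sum_{i<j} (d_{ij} - \hat d_{ij})^2 / \sum_{i<j} d_{ij}^2},}
#' where \eqn{d} are configuration distances and \eqn{\hat d} the isotonic
#' (monotone) regression of \eqn{d} on the rank order of the input
#' dissimilarities (primary tie handling). Each iteration alternates the
#' isotonic fit with a Guttman majorization update of the configuration; a
#' step-halving guard accepts an update only if it does not increase stress,
#' so the recorded stress trace is monotone non-increasing. The first start
#' is the classical-scaling (principal coordinates) configuration; remaining
#' starts are random, and the best final stress wins. Deterministic under
#' `seed`.
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal.
#' @param dims embedding dimension (default 2).
#' @param n_starts number of initializations including the metric start
#'   (default 20).
#' @param seed integer seed for the random starts.
#' @param max_iter maximum iterations per start (default 200).
#' @param tol relative stress-improvement convergence tolerance.
#' @return list with `points` (n x dims coordinates), `stress` (final
#'   stress-1), `trace` (per-iteration stress of the winning start), and
#'   `start_stress` (final stress of every start).
#' @export
nmds <- function(diss, dims = 2, n_starts = 20, seed = 1, max_iter = 200,
                 tol = 1e-7) {
  diss <- as.matrix(diss)
  if (!isSymmetric(unname(diss), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(diss)
  if (n < dims + 2L) stop("need at least dims + 2 samples", call. = FALSE)
  low <- lower.tri(diss)
  delta <- diss[low]
  dvec_order <- function(dd) order(delta, dd)  # primary approach to ties

  stress_parts <- function(X) {
    dd <- dist(X)
    dd <- as.vector(dd)
    ord <- dvec_order(dd)
    dhat <- numeric(length(dd))
    dhat[ord] <- isoreg(dd[ord])$yf
    list(dd = dd, dhat = dhat,
         stress = sqrt(sum((dd - dhat)^2) / sum(dd^2)))
  }

  guttman <- function(X, dd, dhat) {
    B <- matrix(0, n, n)
    ratio <- ifelse(dd > 0, dhat / dd, 0)
    B[low] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    B %*% X / n
  }

  run_start <- function(X) {
    sp <- stress_parts(X)
    trace <- sp$stress
    for (it in seq_len(max_iter)) {
      Xn <- guttman(X, sp$dd, sp$dhat)
      spn <- stress_parts(Xn)
      halvings <- 0L
      while (spn$stress > sp$stress && halvings < 10L) {
        Xn <- (X + Xn) / 2
        spn <- stress_parts(Xn)
        halvings <- halvings + 1L
      }
      if (spn$stress > sp$stress) break
      improved <- sp$stress - spn$stress
      X <- Xn
      sp <- spn
      trace <- c(trace, sp$stress)
      if (improved < tol * max(sp$stress, .Machine$double.eps)) break
    }
    list(points = X, stress = sp$stress, trace = trace)
  }

  # metric start: classical scaling, zero-padded if rank-deficient
  X0 <- cmdscale(diss, k = dims)
  if (ncol(X0) < dims) X0 <- cbind(X0, matrix(0, n, dims - ncol(X0)))
  best <- NULL
  start_stress <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    X <- if (s == 1L) X0 else {
      set.seed(derive_seed(seed, 100L + s))
      matrix(rnorm(n * dims), n, dims) * mean(delta)
    }
    res <- run_start(X)
    start_stress[s] <- res$stress
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  rownames(best$points) <- rownames(diss)
  c(best, list(start_stress = start_stress))
}
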