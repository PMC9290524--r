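# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# gene-by-sample matrix with canonical dimnames
make_expr <- function(values, n_genes = nrow(values), n_samples = ncol(values)) {
  m <- matrix(values, n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# vector with an exact sample correlation `r` to `x` (Gram-Schmidt mix)
make_correlated_vector <- function(x, r, seed = 1) {
  set.seed(seed)
  zx <- (x - mean(x)) / sd(x)
  e <- rnorm(length(x))
  e <- residuals(lm(e ~ zx))
  ze <- e / sd(e)
  r * zx + sqrt(1 - r^2) * ze
}

# n x k data matrix whose sample correlation matrix is exactly C
make_correlated_data <- function(n, C, seed = 1) {
  set.seed(seed)
  k <- ncol(C)
  X <- matrix(rnorm(n * k), n, k)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- qr.Q(qr(X))            # orthonormal columns, zero mean (approximately)
  X <- scale(X, center = TRUE, scale = TRUE)
  # re-orthonormalize after centering for exactness
  X <- qr.Q(qr(scale(X, center = TRUE, scale = FALSE)))
  X <- X %*% chol(C)
  X <- scale(X)               # unit variance columns, correlations = C
  colnames(X) <- paste0("f", seq_len(k))
  X
}

# brute-force triple-loop TOM oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    den <- min(k[i], k[j]) + 1 - a[i, j]
    out[i, j] <- if (den > 0) num / den else 0
  }
  out
}

# random symmetric adjacency with unit diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# exact hypergeometric upper-tail oracle for a 2x2 enrichment table
hyper_tail_oracle <- function(a, b, c, d) {
  K <- a + c      # annotated genes in the universe
  n <- a + b      # gene-set size
  N <- a + b + c + d
  sum(dhyper(a:min(K, n), K, N - K, n))
}

# elementwise Bray-Curtis oracle
bray_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  out
}

# small expression fixture with two planted, well-separated modules
two_block_expr <- function(n_per = 5, n_samples = 12, seed = 42) {
  set.seed(seed)
  e1 <- rnorm(n_samples)
  e2 <- rnorm(n_samples)
  x <- rbind(t(replicate(n_per, e1 + rnorm(n_samples, sd = 0.01))),
             t(replicate(n_per, e2 + rnorm(n_samples, sd = 0.01))))
  make_expr(x)
}

# strip dimnames/attributes for bare-matrix comparisons
drop_attrs <- function(m) matrix(as.numeric(m), nrow(m))
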