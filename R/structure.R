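#' Decompose a module into k-means submodules under correlation distance
#'
#' Each member gene is z-scored across samples, after which squared Euclidean
#' distance is monotone in centered Pearson correlation distance `1 - r`;
#' k-means on the z-scored rows therefore clusters by profile shape. The best
#' of `n_restarts` random initializations (by total within-cluster sum of
#' squares) is kept, deterministically under `seed`.
#'
#' @param expr expression matrix (genes x samples).
#' @param genes member genes of the parent module (length >= k).
#' @param k number of submodules (default 5, must be >= 2).
#' @param seed integer seed.
#' @param n_restarts k-means restarts (default 20).
#' @param eigengene optional parent-module eigengene; when given, the mean
#'   member kME per submodule is reported.
#' @return object of class `submodule_set`: list with `labels` (named
#'   integer vector in 1..k), `k`, `centroids`, `withinss`, and
#'   `mean_kme` (per-submodule mean correlation with `eigengene`, or NULL).
#' @export
kmeans_submodules <- function(expr, genes, k = 5, seed = 1, n_restarts = 20,
                              eigengene = NULL) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (length(genes) < k) stop("module smaller than k", call. = FALSE)
  z <- zscore_rows(expr[genes, , drop = FALSE])
  set.seed(derive_seed(seed, 11L))
  km <- kmeans(z, centers = k, nstart = n_restarts, iter.max = 100L)
  labels <- setNames(km$cluster, genes)
  mean_kme <- NULL
  if (!is.null(eigengene)) {
    kme <- as.numeric(cor(t(expr[genes, , drop = FALSE]), eigengene))
    mean_kme <- tapply(kme, labels, mean)
  }
  structure(list(labels = labels, k = k, centroids = km$centers,
                 withinss = km$tot.withinss, mean_kme = mean_kme),
            class = "submodule_set")
}

#' PCA of a module's member genes
#'
#' Genes are the observations: member rows are z-scored across samples and
#' decomposed by SVD (no further column centering, so a module of identical
#' profiles is rank 1 with all variance on PC1). Gene scores on the leading
#' components separate functional subgroups of the module.
#'
#' @param expr expression matrix.
#' @param genes member genes (>= 3), over >= 3 samples.
#' @param n_components components to return (default 2).
#' @return list with `scores` (gene x component matrix) and `var_explained`
#'   (fractions of total variance, non-increasing).
#' @export
module_pca <- function(expr, genes, n_components = 2) {
  if (length(genes) < 3L || ncol(expr) < 3L) {
    stop("module PCA needs at least 3 genes and 3 samples", call. = FALSE)
  }
  z <- zscore_rows(expr[genes, , drop = FALSE])
  sv <- svd(z)
  if (sv$d[1L] < 1e-12) stop("degenerate module: rank 0", call. = FALSE)
  nc <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(nc), drop = FALSE] %*% diag(sv$d[seq_len(nc)], nc)
  dimnames(scores) <- list(genes, paste0("PC", seq_len(nc)))
  list(scores = scores, var_explained = (sv$d^2 / sum(sv$d^2))[seq_len(nc)])
}

#' GO term over-representation by Fisher's exact test
#'
#' For every term annotating at least one universe gene, a one-sided
#' (greater) Fisher's exact test is run on the 2x2 table of annotated /
#' unannotated genes inside and outside the gene set, and p-values are
#' Benjamini-Hochberg adjusted across all tested terms.
#'
#' @param genes gene set (subset of the universe).
#' @param annotation a [gene_annotation()].
#' @param fdr_threshold FDR cutoff for the returned enriched terms (default
#'   0.05; module-level analyses conventionally use 0.01).
#' @param universe optional universe override (default: all annotated genes).
#' @param all return all tested terms instead of only those below the
#'   threshold (default FALSE).
#' @return data.frame sorted by p: `term`, `set_annotated`, `set_total`,
#'   `bg_annotated`, `bg_total`, `odds_ratio`, `p`, `fdr`.
#' @export
go_enrichment <- function(genes, annotation, fdr_threshold = 0.05,
                          universe = NULL, all = FALSE) {
  if (is.null(universe)) universe <- annotation$universe
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!all(genes %in% universe)) stop("genes must be a subset of the universe", call. = FALSE)
  terms <- annotation$terms[universe]
  gene2terms <- terms
  term_genes <- split(rep(names(gene2terms), lengths(gene2terms)),
                      unlist(gene2terms, use.names = FALSE))
  if (!length(term_genes)) {
    warning("no term annotates any universe gene")
    return(data.frame(term = character(), set_annotated = integer(),
                      set_total = integer(), bg_annotated = integer(),
                      bg_total = integer(), odds_ratio = numeric(),
                      p = numeric(), fdr = numeric()))
  }
  n_set <- length(genes)
  n_bg <- length(universe) - n_set
  res <- lapply(names(term_genes), function(tm) {
    ann <- term_genes[[tm]]
    a <- sum(ann %in% genes)           # in-set annotated
    b <- n_set - a                     # in-set unannotated
    c_ <- length(ann) - a              # background annotated
    d <- n_bg - c_
    ft <- enrichment_test(a, b, c_, d)
    data.frame(term = tm, set_annotated = a, set_total = n_set,
               bg_annotated = c_, bg_total = n_bg,
               odds_ratio = ft$odds_ratio, p = ft$p)
  })
  res <- do.call(rbind, res)
  res$fdr <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  if (!all) res <- res[res$fdr < fdr_threshold, , drop = FALSE]
  res
}

#' One-sided (greater) Fisher's exact test on a 2x2 enrichment table
#'
#' Table layout: `a` in-set annotated, `b` in-set unannotated, `c` background
#' annotated, `d` background unannotated.
#' @param a,b,c,d nonnegative cell counts.
#' @return list with `p` and `odds_ratio` (conditional MLE).
#' @export
enrichment_test <- function(a, b, c, d) {
  ft <- fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                    alternative = "greater")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Write an enrichment table to TSV
#' @param enrichment data.frame from [go_enrichment()].
#' @param path output path.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  write.table(enrichment, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
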